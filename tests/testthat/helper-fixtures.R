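# randomized but always-valid glyph definitions for round-trip properties;
# coordinates stay on integers/half-integers so every value serializes
# exactly within 9 significant digits

random_valid_glyph <- function(tag = "G") {
  w <- sample(10:50, 1)
  h <- sample(6:30, 1)
  defaults <- c(width = w, height = h)
  x_pool <- list(list(t = "0", v = 0),
                 list(t = "{width}", v = w),
                 list(t = "{width/2}", v = w / 2),
                 list(t = "{width - 2}", v = w - 2),
                 list(t = "{width/4 + 1}", v = w / 4 + 1))
  y_pool <- list(list(t = "0", v = 0),
                 list(t = "{-height}", v = -h),
                 list(t = "{-height/2}", v = -h / 2),
                 list(t = "{-height + 1}", v = -h + 1))
  fills <- c("green", "orange", "cornflowerblue", "gray", "plum")
  n_paths <- sample(1:3, 1)
  paths <- lapply(seq_len(n_paths), function(k) {
    npts <- sample(2:5, 1)
    pts <- vapply(seq_len(npts), function(j) {
      x <- x_pool[[sample(length(x_pool), 1)]]
      y <- y_pool[[sample(length(y_pool), 1)]]
      sprintf("%s %s", x$t, y$t)
    }, character(1))
    tpl <- paste0("M ", pts[1],
                  paste0(" L ", pts[-1], collapse = ""),
                  if (stats::runif(1) < 0.5) " Z" else "")
    parametric_path(sprintf("path%d", k), parametric_d = tpl,
                    style = list(fill = sample(fills, 1), stroke = "black",
                                 stroke_width = sample(c(1, 1.5, 2), 1)),
                    defaults = defaults)
  })
  glyph_definition(
    paste0(tag, sample(1e6, 1)), paths, defaults,
    baseline_d = "M 0 0 L {width} 0",
    bounding_box_d = "M 0 {-height} L {width} {-height} L {width} 0 L 0 0 Z")
}

glyphs_semantically_equal <- function(a, b) {
  same_path <- function(p, q) {
    identical(p$name, q$name) &&
      identical(p$static_d, q$static_d) &&
      identical(p$parametric_d, q$parametric_d) &&
      identical(p$style[order(names(p$style))], q$style[order(names(q$style))])
  }
  identical(a$glyph_type, b$glyph_type) &&
    isTRUE(all.equal(a$defaults, b$defaults, tolerance = 1e-12)) &&
    length(a$paths) == length(b$paths) &&
    all(mapply(same_path, a$paths, b$paths)) &&
    isTRUE(all.equal(glyph_baseline(a), glyph_baseline(b), tolerance = 1e-9)) &&
    isTRUE(all.equal(glyph_bounding_box(a), glyph_bounding_box(b), tolerance = 1e-9))
}

svg_path_ids <- function(svg) {
  doc <- xml2::read_xml(svg)
  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='path']")
  xml2::xml_attr(nodes, "id")
}

svg_path_d <- function(svg, id) {
  doc <- xml2::read_xml(svg)
  nd <- xml2::xml_find_first(doc, sprintf(".//*[local-name()='path'][@id='%s']", id))
  xml2::xml_attr(nd, "d")
}

svg_path_style <- function(svg, id) {
  doc <- xml2::read_xml(svg)
  nd <- xml2::xml_find_first(doc, sprintf(".//*[local-name()='path'][@id='%s']", id))
  xml2::xml_attr(nd, "style")
}

# two-feature GenBank record with exactly known CDS lengths
genbank_two_cds <- function(len1 = 300, len2 = 600, strand2 = "+") {
  loc2 <- sprintf("%d..%d", 1000, 1000 + len2 - 1)
  if (strand2 == "-") loc2 <- sprintf("complement(%s)", loc2)
  c("LOCUS       TWOCDS        2000 bp    DNA     linear   SYN",
    "FEATURES             Location/Qualifiers",
    sprintf("     CDS             %d..%d", 100, 100 + len1 - 1),
    "                     /gene=\"a1\"",
    "                     /product=\"DNA polymerase\"",
    sprintf("     CDS             %s", loc2),
    "                     /gene=\"a2\"",
    "                     /product=\"hypothetical protein\"",
    "ORIGIN", "//")
}
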