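test_that("the bundled library holds the seven expected glyphs and validates", {
  lib <- make_fixture_library()
  expect_s3_class(lib, "glyph_library")
  expect_setequal(names(lib), c("Promoter", "RBS", "CDS", "Terminator",
                                "RecombinationSite", "Protein", "SmallMolecule"))
  for (g in lib) expect_silent(validate_glyph(g))
})

test_that("the CDS pentagon at defaults has a 20-unit body and apex at 30", {
  g <- make_fixture_library()$CDS
  body <- parse_path_data(g$paths[[1]]$static_d)
  xs <- unlist(lapply(body, function(c) if (length(c$args)) c$args[seq(1, length(c$args), 2)]))
  expect_equal(max(xs), 30)                      # head apex
  body_xs <- xs[xs < max(xs)]
  expect_equal(range(body_xs), c(0, 20))         # body = width - arrowhead_width
  expect_equal(unname(glyph_baseline(g)$end - glyph_baseline(g)$start), c(30, 0))
})

test_that("stretching the CDS widens the body but never the head", {
  g <- make_fixture_library()$CDS
  head_span <- function(w) {
    d <- evaluate_template(g$paths[[1]]$parametric_d,
                           resolve_parameters(g, c(width = w)))
    cmds <- parse_path_data(d)
    xs <- unlist(lapply(cmds, function(c) if (length(c$args)) c$args[seq(1, length(c$args), 2)]))
    max(xs) - sort(unique(xs), decreasing = TRUE)[2]
  }
  expect_equal(head_span(30), 10)
  expect_equal(head_span(60), 10)
  expect_equal(head_span(95), 10)
})

test_that("every parametric template reproduces its static path at the defaults", {
  lib <- make_fixture_library()
  worst <- 0
  for (g in lib) {
    for (p in g$paths) {
      if (is.null(p$parametric_d)) next
      got <- parse_path_data(evaluate_template(p$parametric_d, g$defaults))
      ref <- parse_path_data(p$static_d)
      dev <- sbolvis:::command_deviation(ref, got)
      expect_false(is.na(dev))
      worst <- max(worst, dev)
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("write/read round-trips every bundled glyph semantically", {
  lib <- make_fixture_library()
  for (g in lib) {
    g2 <- read_glyph(write_glyph(g))
    expect_true(glyphs_semantically_equal(g, g2), label = g$glyph_type)
  }
})

test_that("write/read round-trips randomly generated valid glyphs", {
  set.seed(123)
  for (i in 1:50) {
    g <- random_valid_glyph()
    g2 <- read_glyph(write_glyph(g))
    expect_true(glyphs_semantically_equal(g, g2))
  }
})

test_that("stripping parametric attributes leaves valid static SVG", {
  lib <- make_fixture_library()
  for (g in lib) {
    psvg <- write_glyph(g)
    doc <- xml2::read_xml(psvg)
    before <- xml2::xml_attr(xml2::xml_find_all(doc, ".//*[local-name()='path']"), "d")
    stripped <- gsub(" (xmlns:)?parametric(:[A-Za-z-]+)?=\"[^\"]*\"", "", psvg)
    generic <- xml2::read_xml(stripped) # a plain XML/SVG parser accepts it
    expect_false(grepl("parametric", stripped, fixed = TRUE))
    after <- xml2::xml_attr(xml2::xml_find_all(generic, ".//*[local-name()='path']"), "d")
    expect_identical(after, before)
    for (d in after) expect_silent(parse_path_data(d))
  }
})

test_that("defaults must close over every referenced parameter", {
  bad <- paste0(
    "<svg xmlns=\"http://www.w3.org/2000/svg\" ",
    "xmlns:parametric=\"https://parametric-svg.github.io/v0.2\" ",
    "parametric:type=\"X\" parametric:defaults=\"height=4\">",
    "<path id=\"p\" d=\"M 0 0 L 30 0\" parametric:d=\"M 0 0 L {width} 0\"/>",
    "<path id=\"baseline\" d=\"M 0 0 L 30 0\"/>",
    "<path id=\"bounding-box\" d=\"M 0 -4 L 30 -4 L 30 0 L 0 0 Z\"/></svg>")
  expect_error(read_glyph(bad), "'width'")
  expect_error(read_glyph(bad), "'p'")
})

test_that("glyphs violating structural invariants are refused", {
  lib <- make_fixture_library()
  g <- lib$CDS
  dup <- g
  dup$paths <- c(g$paths, g$paths)
  expect_error(write_glyph(dup), "duplicate path name")
  tilted <- g
  tilted$baseline_d <- "M 0 0 L {width} 3"
  expect_error(validate_glyph(tilted), "not horizontal")
  short_bl <- g
  short_bl$baseline_d <- "M 0 0 L {width/2} 0"
  expect_error(validate_glyph(short_bl), "span the bounding box")
  drifted <- g
  drifted$paths[[1]]$static_d <- "M 0 -7.5 L 20 -7.5 L 30 0 L 20 7.5 L 0 7.6 Z"
  expect_error(validate_glyph(drifted), "does not reproduce")
})

test_that("a plain SVG with markers loads as a degenerate pSVG", {
  plain <- paste0(
    "<svg xmlns=\"http://www.w3.org/2000/svg\">",
    "<path id=\"body\" d=\"M 0 0 L 10 0 L 5 -8 Z\"/>",
    "<path id=\"baseline\" d=\"M 0 0 L 10 0\"/>",
    "<path id=\"bounding-box\" d=\"M 0 -8 L 10 -8 L 10 0 L 0 0 Z\"/></svg>")
  g <- read_glyph(plain, glyph_type = "PlainArrow")
  expect_identical(length(g$defaults), 0L)
  expect_identical(length(g$paths), 1L)
  expect_null(g$paths[[1]]$parametric_d)
})

test_that("library loading enforces content and uniqueness", {
  dir <- withr::local_tempdir()
  lib <- make_fixture_library(dir)
  loaded <- load_library(dir)
  expect_identical(length(loaded), 7L)
  expect_setequal(names(loaded), names(lib))
  # duplicate glyph type across two files
  write_glyph(lib$CDS, file.path(dir, "cds-copy.psvg"))
  expect_error(load_library(dir), "duplicate glyph type 'CDS'")
  empty <- withr::local_tempdir()
  expect_error(load_library(empty), "no pSVG files")
})

test_that("the installed glyph files equal the in-memory generator output", {
  dir <- system.file("extdata", "glyphs", package = "sbolvis")
  loaded <- load_library(dir)
  lib <- make_fixture_library()
  expect_setequal(names(loaded), names(lib))
  for (nm in names(lib)) {
    expect_true(glyphs_semantically_equal(loaded[[nm]], lib[[nm]]), label = nm)
  }
})

test_that("non-strict loading skips invalid files with a warning", {
  dir <- withr::local_tempdir()
  make_fixture_library(dir)
  writeLines("<svg xmlns='http://www.w3.org/2000/svg'></svg>",
             file.path(dir, "broken.psvg"))
  expect_error(load_library(dir), "broken.psvg")
  expect_warning(lib <- load_library(dir, strict = FALSE), "broken.psvg")
  expect_identical(length(lib), 7L)
})
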