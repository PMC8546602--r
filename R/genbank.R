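#' Read the feature table of a GenBank flat file
#'
#' A minimal reader for annotated GenBank records: it extracts the LOCUS
#' name and length and every entry of the FEATURES table with its location
#' and qualifiers. Locations use the GenBank convention (1-based, inclusive);
#' `complement(...)` marks the reverse strand and joined/compound locations
#' are collapsed to their overall span (minimum start to maximum end).
#' Sequence data under ORIGIN is ignored.
#'
#' @param file Path to a GenBank flat file, or a character vector of its
#'   lines.
#' @return A list of class `genbank_record`: `name`, `length`, and
#'   `features`, a tibble with columns `key`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`) and `qualifiers` (list of named character vectors).
#' @export
read_genbank <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE))
  }
  if (length(lines) == 0L) stop("empty GenBank input", call. = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  name <- NA_character_
  len <- NA_integer_
  if (length(locus)) {
    flds <- strsplit(trimws(locus[1]), "[[:space:]]+")[[1]]
    if (length(flds) >= 2L) name <- flds[2]
    bpidx <- which(flds == "bp")
    if (length(bpidx) && bpidx[1] > 1L) {
      len <- suppressWarnings(as.integer(flds[bpidx[1] - 1L]))
    }
  } else {
    stop("not a GenBank flat file: no LOCUS line", call. = FALSE)
  }
  fstart <- grep("^FEATURES", lines)
  feats <- empty_genbank_features()
  if (length(fstart)) {
    i <- fstart[1] + 1L
    cur <- NULL
    flush <- function(cur, feats) {
      if (is.null(cur)) return(feats)
      dplyr::bind_rows(feats, tibble::tibble(
        key = cur$key, start = cur$start, end = cur$end, strand = cur$strand,
        qualifiers = list(cur$quals)))
    }
    while (i <= length(lines)) {
      ln <- lines[i]
      if (grepl("^(ORIGIN|CONTIG|//)", ln)) break
      if (grepl("^ {5}[A-Za-z]", ln)) {
        feats <- flush(cur, feats)
        key <- trimws(substr(ln, 1, 21))
        loc <- trimws(substr(ln, 22, nchar(ln)))
        cur <- c(parse_genbank_location(loc), list(key = key, quals = character(0)))
      } else if (!is.null(cur) && grepl("^ {10,}/", trimws(ln, "right"))) {
        q <- sub("^[[:space:]]*/", "", ln)
        eq <- regexpr("=", q, fixed = TRUE)
        if (eq > 0) {
          qname <- substr(q, 1, eq - 1L)
          qval <- gsub("^\"|\"$", "", trimws(substr(q, eq + 1L, nchar(q))))
          cur$quals[qname] <- qval
        } else {
          cur$quals[trimws(q)] <- ""
        }
      }
      # continuation lines of long qualifier values are ignored
      i <- i + 1L
    }
    feats <- flush(cur, feats)
  }
  structure(list(name = name, length = len, features = feats),
            class = "genbank_record")
}

empty_genbank_features <- function() {
  tibble::tibble(key = character(0), start = integer(0), end = integer(0),
                 strand = character(0), qualifiers = list())
}

parse_genbank_location <- function(loc) {
  strand <- if (grepl("^complement", loc)) "-" else "+"
  nums <- suppressWarnings(as.integer(
    regmatches(loc, gregexpr("[0-9]+", loc))[[1]]))
  if (length(nums) == 0L || any(is.na(nums))) {
    stop(sprintf("cannot parse feature location '%s'", loc), call. = FALSE)
  }
  list(start = min(nums), end = max(nums), strand = strand)
}

#' @export
print.genbank_record <- function(x, ...) {
  cat(sprintf("<GenBank record '%s': %s bp, %d feature(s)>\n", x$name,
              ifelse(is.na(x$length), "?", x$length), nrow(x$features)))
  invisible(x)
}

#' Feature-to-glyph mapping rules
#'
#' Controls how GenBank features become parts: which feature keys are
#' retained, how feature length converts to glyph width, and how annotated
#' function maps to color. Color rules are an ordered named vector of
#' case-insensitive substring patterns matched against the `/product` and
#' `/function` qualifiers; the first match wins, otherwise the default.
#'
#' @param scale Canvas units per nucleotide (> 0). The default 0.02 gives a
#'   1 kb CDS a width of 20 units.
#' @param min_width Floor on part width in canvas units (> 0), so very
#'   short features stay visible.
#' @param rules Named character vector `c(pattern = color, ...)` (may be
#'   empty).
#' @param retained_keys Feature keys to keep (default only `CDS`).
#' @param default_color Fill used when no rule matches.
#' @return A list of class `feature_mapping`.
#' @export
feature_mapping <- function(scale = 0.02, min_width = 8, rules = character(0),
                            retained_keys = "CDS", default_color = "gray") {
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  if (min_width <= 0) stop("min_width must be positive", call. = FALSE)
  if (length(rules) && (is.null(names(rules)) || any(!nzchar(names(rules))))) {
    stop("color rules must be a named vector: c(pattern = color)", call. = FALSE)
  }
  structure(list(scale = scale, min_width = min_width, rules = rules,
                 retained_keys = retained_keys, default_color = default_color),
            class = "feature_mapping")
}

#' Read color-mapping rules from a config file
#'
#' One `pattern=color` rule per line, in priority order; blank lines and
#' `#` comments are ignored.
#' @param file Path to the rules file.
#' @return Named character vector usable as `rules` in [feature_mapping()].
#' @export
read_color_rules <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(character(0))
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, function(p) length(p) != 2L, logical(1))
  if (any(bad)) {
    stop(sprintf("malformed color rule: '%s'", lines[bad][1]), call. = FALSE)
  }
  stats::setNames(trimws(vapply(kv, `[[`, character(1), 2L)),
                  trimws(vapply(kv, `[[`, character(1), 1L)))
}

feature_color <- function(quals, mapping) {
  text <- tolower(paste(quals[names(quals) %in% c("product", "function")],
                        collapse = " "))
  for (pat in names(mapping$rules)) {
    if (nzchar(text) && grepl(tolower(pat), text, fixed = TRUE)) {
      return(mapping$rules[[pat]])
    }
  }
  mapping$default_color
}

#' Convert a GenBank record to a parts table
#'
#' One part per retained feature (default: CDS only), ordered by start
#' coordinate. Width hints are proportional to feature length
#' (`length x scale`, floored at `min_width`), so coding regions appear at
#' their correct relative sizes; complement-strand features are reversed;
#' fill color comes from the first matching qualifier rule. Feature
#' coordinates are 1-based inclusive, so length is `end - start + 1`.
#'
#' @param record A `genbank_record` from [read_genbank()] (or a file path).
#' @param mapping A [feature_mapping()].
#' @return A parts table (possibly empty, with a warning when the record
#'   has features but none are retained).
#' @export
genbank_to_parts <- function(record, mapping = feature_mapping()) {
  if (is.character(record)) record <- read_genbank(record)
  feats <- record$features
  keep <- feats[feats$key %in% mapping$retained_keys, , drop = FALSE]
  if (nrow(keep) == 0L) {
    warning("no retained features in record; empty parts table", call. = FALSE)
    return(empty_parts())
  }
  keep <- keep[order(keep$start), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    ft <- keep[i, ]
    len <- ft$end - ft$start + 1L
    quals <- ft$qualifiers[[1]]
    lbl <- if ("gene" %in% names(quals)) quals[["gene"]] else NA_character_
    part("CDS",
         orientation = if (ft$strand == "-") "reverse" else "forward",
         user_style = list(body = list(fill = feature_color(quals, mapping))),
         label = lbl,
         width_hint = max(mapping$min_width, len * mapping$scale))
  })
  dplyr::bind_rows(rows)
}

#' Render a GenBank record as a wrapped SBOL Visual diagram
#'
#' Converts the record with [genbank_to_parts()], wraps rows at
#' `max_line_width`, and renders with [render_construct()]; rows read in
#' genomic order left-to-right, top-to-bottom.
#'
#' @inheritParams genbank_to_parts
#' @param max_line_width Row width at which the design wraps (units).
#' @param canvas An [svg_canvas()].
#' @param part_spacing,line_spacing,start Passed to [construct_spec()].
#' @return Union bounds of the drawing.
#' @export
render_genbank <- function(record, mapping = feature_mapping(),
                           max_line_width = 200, canvas = svg_canvas(),
                           part_spacing = 4, line_spacing = 40, start = c(0, 0)) {
  prts <- genbank_to_parts(record, mapping)
  spec <- construct_spec(prts, part_spacing = part_spacing, start = start,
                         max_line_width = max_line_width,
                         line_spacing = line_spacing)
  render_construct(spec, make_fixture_library(), canvas)
}

#' Generate a deterministic synthetic GenBank record
#'
#' Emits a small, fully synthetic annotated record for testing and
#' demonstration: `n_cds` CDS features with pseudo-random lengths, strands,
#' gene names and `/product` annotations drawn from a fixed vocabulary.
#' The same seed always yields byte-identical text.
#'
#' @param n_cds Number of CDS features (>= 1).
#' @param seed Integer seed.
#' @param file Optional path to write the record to.
#' @return The record text as a character vector of lines (invisibly when
#'   written to `file`).
#' @export
genbank_fixture <- function(n_cds = 12, seed = 1, file = NULL) {
  if (n_cds < 1) stop("n_cds must be at least 1", call. = FALSE)
  products <- c("DNA polymerase", "RNA polymerase subunit", "ABC transporter",
                "histidine kinase", "ribosomal protein", "hypothetical protein",
                "membrane permease", "transcriptional regulator")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  lens <- sample(150:1500, n_cds, replace = TRUE)
  gaps <- sample(50:400, n_cds, replace = TRUE)
  strands <- sample(c("+", "-"), n_cds, replace = TRUE)
  prods <- sample(products, n_cds, replace = TRUE)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  starts <- cumsum(gaps + c(0, lens[-n_cds]))
  ends <- starts + lens - 1L
  total <- ends[n_cds] + 100L
  out <- c(
    sprintf("LOCUS       SYN%06d %10d bp    DNA     linear   SYN", seed, total),
    "DEFINITION  synthetic test record (generated fixture).",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", total))
  for (i in seq_len(n_cds)) {
    loc <- sprintf("%d..%d", starts[i], ends[i])
    if (strands[i] == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out,
             sprintf("     CDS             %s", loc),
             sprintf("                     /gene=\"syn%02d\"", i),
             sprintf("                     /product=\"%s\"", prods[i]))
  }
  out <- c(out, "ORIGIN", "//")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
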