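SHORTHAND_CODES <- c(p = "Promoter", r = "RBS", c = "CDS", t = "Terminator",
                     x = "RecombinationSite")

#' Parse a design shorthand string
#'
#' The command-line shorthand describes a construct as whitespace-separated
#' tokens, one per part: an optional `<` prefix reversing the part's
#' direction, a one-letter type code (`p` = promoter, `r` = RBS, `c` = CDS,
#' `t` = terminator, `x` = recombination site), and an optional `.color`
#' suffix applied as the fill of the glyph's primary (first) path. Color
#' names may carry the `l_` prefix for a 50%-toward-white lighter version,
#' e.g. `"p r c.l_blue t"` or `"<c.red"`.
#'
#' @param s A non-empty design string.
#' @return A parts table (see [part()]).
#' @examples
#' parse_design_string("p r c.green t")
#' @export
parse_design_string <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(trimws(s))) {
    stop("design string must be a single non-empty string", call. = FALSE)
  }
  tokens <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  rows <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    m <- regmatches(tok, regexec(
      "^(<?)([A-Za-z])(\\.([A-Za-z_][A-Za-z0-9_]*|#[0-9a-fA-F]{6}|#[0-9a-fA-F]{3}))?$",
      tok))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("malformed design token '%s' at position %d", tok, i), call. = FALSE)
    }
    code <- m[3]
    if (!(code %in% names(SHORTHAND_CODES))) {
      stop(sprintf("unknown part code '%s' in token '%s' at position %d (valid: %s)",
                   code, tok, i, paste(names(SHORTHAND_CODES), collapse = ", ")),
           call. = FALSE)
    }
    glyph_type <- SHORTHAND_CODES[[code]]
    orientation <- if (m[2] == "<") "reverse" else "forward"
    style <- list()
    if (nzchar(m[5])) {
      col <- if (startsWith(m[5], "l_")) lighten_color(m[5]) else resolve_color(m[5])
      style <- stats::setNames(list(list(fill = col)), primary_path_name(glyph_type))
    }
    rows[[i]] <- part(glyph_type, orientation = orientation, user_style = style)
  }
  dplyr::bind_rows(rows)
}

# the path a shorthand color applies to: first visible path of the fixture
primary_path_name <- function(glyph_type) {
  switch(glyph_type,
    Promoter = "stem", RBS = "disc", CDS = "body", Terminator = "stem",
    RecombinationSite = "triangle", "body")
}

#' Serialize a parts table back to shorthand
#'
#' Inverse of [parse_design_string()] up to color canonicalization (colors
#' reappear as hex tokens). Parts whose glyph type has no shorthand code
#' are refused.
#' @param parts A parts table.
#' @return A single design string.
#' @export
serialize_design_string <- function(parts) {
  code_of <- stats::setNames(names(SHORTHAND_CODES), SHORTHAND_CODES)
  toks <- vapply(seq_len(nrow(parts)), function(i) {
    prt <- parts[i, ]
    if (!(prt$glyph_type %in% names(code_of))) {
      stop(sprintf("glyph type '%s' has no shorthand code", prt$glyph_type),
           call. = FALSE)
    }
    tok <- code_of[[prt$glyph_type]]
    st <- prt$user_style[[1]]
    fill <- if (length(st)) st[[1]]$fill else NULL
    if (!is.null(fill)) tok <- paste0(tok, ".", fill)
    if (prt$orientation == "reverse") tok <- paste0("<", tok)
    tok
  }, character(1))
  paste(toks, collapse = " ")
}

#' Parse an interaction shorthand string
#'
#' Four `//`-separated fields: 0-based start part index, end part index,
#' type code (`in` = inhibition, `co` = control) and color, e.g.
#' `"0//2//in//red"`.
#'
#' @param s A non-empty interaction string.
#' @return A one-row interactions table (see [interaction()]).
#' @export
parse_interaction_string <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(trimws(s))) {
    stop("interaction string must be a single non-empty string", call. = FALSE)
  }
  fields <- strsplit(trimws(s), "//", fixed = TRUE)[[1]]
  if (length(fields) != 4L) {
    stop(sprintf("interaction '%s' must have 4 '//'-separated fields (start//end//type//color), got %d",
                 s, length(fields)), call. = FALSE)
  }
  idx <- suppressWarnings(as.integer(fields[1:2]))
  if (any(is.na(idx)) || any(as.numeric(fields[1:2]) != idx)) {
    stop(sprintf("interaction '%s': indices must be integers", s), call. = FALSE)
  }
  kind <- switch(fields[3], "in" = "inhibition", "co" = "control",
                 stop(sprintf("interaction '%s': unknown type code '%s' (valid: in, co)",
                              s, fields[3]), call. = FALSE))
  color <- if (startsWith(fields[4], "l_")) lighten_color(fields[4]) else fields[4]
  interaction(idx[1], idx[2], kind, color)
}

#' Lighten a named color by blending halfway to white
#'
#' Implements the shorthand's `l_` color prefix: each RGB channel of the
#' base color is moved 50% toward 255 and the result returned as hex, so
#' `"l_blue"` is `#8080ff` (RGB 128, 128, 255) and white is a fixed point.
#'
#' @param name Either `"l_<color>"` or a bare base color name.
#' @return A hex color string.
#' @export
lighten_color <- function(name) {
  base <- sub("^l_", "", name)
  if (base == "none" || grepl("^#", base) || !(base %in% grDevices::colors())) {
    if (!grepl("^#([0-9a-fA-F]{6}|[0-9a-fA-F]{3})$", base)) {
      stop(sprintf("unknown base color '%s' in '%s'", base, name), call. = FALSE)
    }
  }
  rgb <- grDevices::col2rgb(base)
  lit <- round(rgb / 2 + 127.5)
  sprintf("#%02x%02x%02x", lit[1], lit[2], lit[3])
}
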