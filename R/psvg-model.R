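PSVG_NS <- "https://parametric-svg.github.io/v0.2"
SVG_NS <- "http://www.w3.org/2000/svg"

#' Construct a parametric path
#'
#' One named path of a glyph: the baked SVG path data (`static_d`, what a
#' plain SVG viewer draws), an optional parametric template (`parametric_d`,
#' same path with `{expression}` coordinates), and the default style.
#'
#' @param name Path name, unique within its glyph (the SVG `id`).
#' @param static_d SVG path data for the default shape. If `NULL` and
#'   `parametric_d` is given together with `defaults`, it is derived by
#'   evaluating the template at the defaults.
#' @param parametric_d Optional path-data template.
#' @param style Named list with any of `fill`, `stroke`, `stroke_width`,
#'   `opacity`.
#' @param defaults Binding used to derive `static_d` when absent.
#' @return A list of class `parametric_path`.
#' @export
parametric_path <- function(name, static_d = NULL, parametric_d = NULL,
                            style = list(), defaults = numeric()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("path name must be a non-empty string", call. = FALSE)
  }
  if (is.null(static_d)) {
    if (is.null(parametric_d)) stop("a path needs static_d or parametric_d", call. = FALSE)
    static_d <- evaluate_template(parametric_d, defaults)
  }
  structure(list(name = name, static_d = static_d, parametric_d = parametric_d,
                 style = normalize_style(style)),
            class = "parametric_path")
}

normalize_style <- function(style) {
  if (is.null(style)) return(list())
  allowed <- c("fill", "stroke", "stroke_width", "opacity")
  bad <- setdiff(names(style), allowed)
  if (length(bad)) {
    stop(sprintf("unknown style field(s): %s (valid: %s)",
                 paste(bad, collapse = ", "), paste(allowed, collapse = ", ")),
         call. = FALSE)
  }
  style[!vapply(style, is.null, logical(1))]
}

#' Construct a glyph definition
#'
#' A glyph is an ordered set of named (optionally parametric) paths, the
#' parameter defaults, and two composition markers: a horizontal baseline
#' segment spanning the bounding box (the DNA strand the glyph sits on; its
#' start is the glyph's anchor, its end locates the next glyph) and the
#' bounding box itself. Both markers may be parametric so they track
#' geometry overrides.
#'
#' @param glyph_type SBOL Visual term, e.g. `"Promoter"`, `"CDS"`.
#' @param paths List of [parametric_path()] objects (visible geometry only).
#' @param defaults Named numeric parameter defaults; must bind every
#'   parameter referenced by any template in the glyph.
#' @param baseline_d Path-data template for the baseline (an `M ... L ...`
#'   horizontal segment).
#' @param bounding_box_d Path-data template for the bounding box outline.
#' @param validate Check all invariants (default `TRUE`).
#' @return An object of class `glyph_definition`.
#' @export
glyph_definition <- function(glyph_type, paths, defaults, baseline_d,
                             bounding_box_d, validate = TRUE) {
  defaults <- as_param_binding(defaults)
  g <- structure(list(glyph_type = glyph_type, paths = paths, defaults = defaults,
                      baseline_d = baseline_d, bounding_box_d = bounding_box_d),
                 class = "glyph_definition")
  if (validate) validate_glyph(g)
  g
}

#' @export
print.glyph_definition <- function(x, ...) {
  cat(sprintf("<glyph '%s': %d path(s); parameters: %s>\n", x$glyph_type,
              length(x$paths),
              if (length(x$defaults)) paste(sprintf("%s=%g", names(x$defaults), x$defaults),
                                            collapse = ", ") else "(none)"))
  invisible(x)
}

#' Baseline segment of a glyph at a parameter binding
#' @param g A `glyph_definition`.
#' @param binding Full parameter binding (defaults when omitted).
#' @return List with `start` and `end` points (`c(x, y)` each).
#' @export
glyph_baseline <- function(g, binding = g$defaults) {
  cmds <- parse_path_data(evaluate_template(g$baseline_d, binding))
  list(start = cmds[[1]]$args, end = cmds[[length(cmds)]]$args)
}

#' Declared bounding box of a glyph at a parameter binding
#' @inheritParams glyph_baseline
#' @return Named numeric `c(xmin, ymin, xmax, ymax)`.
#' @export
glyph_bounding_box <- function(g, binding = g$defaults) {
  path_bounds(evaluate_template(g$bounding_box_d, binding))
}

#' Validate a glyph definition
#'
#' Checks: unique non-empty path names; all path data parses; the defaults
#' bind every referenced parameter (closure); evaluating each parametric
#' template at the defaults reproduces the static path data coordinate-wise
#' to 1e-9; the baseline is horizontal and spans the bounding box; the box
#' has positive width and contains the default geometry to 1e-6.
#'
#' @param g A `glyph_definition`.
#' @return `g`, invisibly; errors describe the first violation.
#' @export
validate_glyph <- function(g) {
  if (!nzchar(g$glyph_type %||% "")) stop("glyph_type must be non-empty", call. = FALSE)
  nms <- vapply(g$paths, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop(sprintf("glyph '%s': duplicate path name(s): %s", g$glyph_type,
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")), call. = FALSE)
  }
  if (is.null(g$baseline_d)) {
    stop(sprintf("glyph '%s': missing baseline", g$glyph_type), call. = FALSE)
  }
  if (is.null(g$bounding_box_d)) {
    stop(sprintf("glyph '%s': missing bounding box", g$glyph_type), call. = FALSE)
  }
  # closure: every referenced parameter has a default
  tpls <- c(stats::setNames(lapply(g$paths, `[[`, "parametric_d"), nms),
            list(baseline = g$baseline_d, `bounding-box` = g$bounding_box_d))
  for (tnm in names(tpls)) {
    tpl <- tpls[[tnm]]
    if (is.null(tpl)) next
    refs <- template_parameters(tpl)
    missing <- setdiff(refs, names(g$defaults))
    if (length(missing)) {
      stop(sprintf("glyph '%s' path '%s': parameter(s) %s referenced but absent from defaults",
                   g$glyph_type, tnm,
                   paste(sprintf("'%s'", missing), collapse = ", ")), call. = FALSE)
    }
  }
  # default-evaluation identity per path
  for (p in g$paths) {
    static_cmds <- parse_path_data(p$static_d)
    if (!is.null(p$parametric_d)) {
      eval_cmds <- parse_path_data(evaluate_template(p$parametric_d, g$defaults))
      dev <- command_deviation(static_cmds, eval_cmds)
      if (is.na(dev) || dev > 1e-9) {
        stop(sprintf("glyph '%s' path '%s': parametric template at defaults does not reproduce static d (max deviation %s)",
                     g$glyph_type, p$name,
                     if (is.na(dev)) "structural mismatch" else format(dev)),
             call. = FALSE)
      }
    }
  }
  bl <- glyph_baseline(g)
  if (abs(bl$start[2] - bl$end[2]) > 1e-9) {
    stop(sprintf("glyph '%s': baseline is not horizontal", g$glyph_type), call. = FALSE)
  }
  box <- glyph_bounding_box(g)
  if (!(box[["xmax"]] > box[["xmin"]])) {
    stop(sprintf("glyph '%s': bounding box must have positive width", g$glyph_type),
         call. = FALSE)
  }
  if (abs(min(bl$start[1], bl$end[1]) - box[["xmin"]]) > 1e-6 ||
      abs(max(bl$start[1], bl$end[1]) - box[["xmax"]]) > 1e-6) {
    stop(sprintf("glyph '%s': baseline must span the bounding box horizontally",
                 g$glyph_type), call. = FALSE)
  }
  for (p in g$paths) {
    b <- path_bounds(p$static_d)
    if (b[["xmin"]] < box[["xmin"]] - 1e-6 || b[["xmax"]] > box[["xmax"]] + 1e-6 ||
        b[["ymin"]] < box[["ymin"]] - 1e-6 || b[["ymax"]] > box[["ymax"]] + 1e-6) {
      stop(sprintf("glyph '%s' path '%s': default geometry exceeds the bounding box",
                   g$glyph_type, p$name), call. = FALSE)
    }
  }
  invisible(g)
}

# max absolute coordinate deviation between two command lists; NA if the
# opcode sequences differ
command_deviation <- function(a, b) {
  if (length(a) != length(b)) return(NA_real_)
  devs <- mapply(function(ca, cb) {
    if (ca$op != cb$op || length(ca$args) != length(cb$args)) return(NA_real_)
    if (length(ca$args) == 0L) return(0)
    max(abs(ca$args - cb$args))
  }, a, b)
  if (any(is.na(devs))) NA_real_ else max(devs, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pSVG glyph definition file
#'
#' A pSVG file is standard SVG whose `path` elements may carry a
#' `parametric:d` template attribute and whose root `svg` element carries
#' `parametric:defaults` (semicolon-separated `name=value` pairs) and
#' `parametric:type` (the SBOL Visual glyph term). Two specially named
#' paths, `id="baseline"` and `id="bounding-box"`, encode the composition
#' markers and are never painted.
#'
#' Plain SVG files (no `parametric:*` attributes at all) are accepted as
#' degenerate pSVG as long as the two marker paths are present: they yield a
#' definition with no parametric paths and empty defaults. For such files
#' the glyph type falls back to the file name.
#'
#' @param file Path to a pSVG file, or a literal XML string.
#' @param glyph_type Optional override for the glyph type when the file
#'   carries no `parametric:type` attribute.
#' @return A validated `glyph_definition`.
#' @export
read_glyph <- function(file, glyph_type = NULL) {
  doc <- xml2::read_xml(file)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "svg") {
    stop("not an SVG document: root element is not <svg>", call. = FALSE)
  }
  nsmap <- tryCatch(xml2::xml_ns(doc), error = function(e) character(0))
  pfx <- names(nsmap)[nsmap == PSVG_NS]
  pfx <- if (length(pfx)) pfx[1] else NA_character_
  pattr <- function(attrs, name) {
    key <- if (!is.na(pfx)) paste0(pfx, ":", name) else NA_character_
    if (!is.na(key) && key %in% names(attrs)) attrs[[key]] else NULL
  }
  rattrs <- if (length(nsmap)) xml2::xml_attrs(root, ns = nsmap) else xml2::xml_attrs(root)
  if (is.null(glyph_type)) {
    glyph_type <- pattr(rattrs, "type") %||%
      if (is.character(file) && length(file) == 1L && !grepl("<", file) &&
          file.exists(file)) {
        sub("\\.p?svg$", "", basename(file))
      } else {
        NA_character_
      }
  }
  defaults <- parse_defaults_attr(pattr(rattrs, "defaults") %||% "")
  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='path']")
  if (length(nodes) == 0L) stop("pSVG file contains no path elements", call. = FALSE)
  paths <- list()
  baseline_d <- NULL
  bounding_box_d <- NULL
  for (nd in nodes) {
    at <- if (length(nsmap)) xml2::xml_attrs(nd, ns = nsmap) else xml2::xml_attrs(nd)
    id <- if ("id" %in% names(at)) at[["id"]] else NA_character_
    d <- if ("d" %in% names(at)) at[["d"]] else NA_character_
    pd <- pattr(at, "d")
    if (is.na(id) || !nzchar(id)) {
      stop("every path element needs a non-empty id attribute", call. = FALSE)
    }
    if (id == "baseline") {
      baseline_d <- pd %||% d
    } else if (id == "bounding-box") {
      bounding_box_d <- pd %||% d
    } else {
      if (is.na(d)) stop(sprintf("path '%s' has no d attribute", id), call. = FALSE)
      paths[[length(paths) + 1L]] <- parametric_path(
        name = id, static_d = d, parametric_d = pd,
        style = parse_style_attr(if ("style" %in% names(at)) at[["style"]] else ""))
    }
  }
  if (is.na(glyph_type)) {
    stop("pSVG file lacks a parametric:type attribute naming the glyph", call. = FALSE)
  }
  glyph_definition(glyph_type, paths, defaults, baseline_d, bounding_box_d)
}

parse_defaults_attr <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) return(as_param_binding(numeric()))
  pairs <- strsplit(s, ";", fixed = TRUE)[[1]]
  pairs <- trimws(pairs)
  pairs <- pairs[nzchar(pairs)]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  bad <- vapply(kv, function(p) length(p) != 2L, logical(1))
  if (any(bad)) {
    stop(sprintf("malformed parametric:defaults entry: '%s'", pairs[bad][1]), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(vapply(kv, `[[`, character(1), 2L)))
  nms <- trimws(vapply(kv, `[[`, character(1), 1L))
  if (any(is.na(vals))) {
    stop(sprintf("non-numeric default for parameter '%s'", nms[is.na(vals)][1]),
         call. = FALSE)
  }
  as_param_binding(stats::setNames(vals, nms))
}

parse_style_attr <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) return(list())
  entries <- strsplit(s, ";", fixed = TRUE)[[1]]
  entries <- trimws(entries)
  entries <- entries[nzchar(entries)]
  out <- list()
  for (e in entries) {
    kv <- strsplit(e, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L) next
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key == "fill") out$fill <- val
    if (key == "stroke") out$stroke <- val
    if (key == "stroke-width") out$stroke_width <- as.numeric(val)
    if (key == "opacity") out$opacity <- as.numeric(val)
  }
  out
}

style_attr_string <- function(style) {
  parts <- character(0)
  if (!is.null(style$fill)) parts <- c(parts, paste0("fill:", style$fill))
  if (!is.null(style$stroke)) parts <- c(parts, paste0("stroke:", style$stroke))
  if (!is.null(style$stroke_width)) {
    parts <- c(parts, paste0("stroke-width:", format_coord(style$stroke_width)))
  }
  if (!is.null(style$opacity)) parts <- c(parts, paste0("opacity:", format_coord(style$opacity)))
  paste(parts, collapse = ";")
}

defaults_attr_string <- function(defaults) {
  if (length(defaults) == 0L) return("")
  paste(sprintf("%s=%s", names(defaults),
                vapply(defaults, format_coord, character(1))), collapse = ";")
}

#' Write a glyph definition as a pSVG document
#'
#' The emitted file is well-formed XML and valid plain SVG: stripping every
#' `parametric:*` attribute leaves a static SVG drawing the default shape,
#' so any SVG consumer can use the file (without customization).
#'
#' @param g A valid `glyph_definition` (invariants are re-checked; an
#'   invalid glyph is refused).
#' @param file Optional output path; when `NULL` the XML is only returned.
#' @return The pSVG document as a single string, invisibly when written.
#' @export
write_glyph <- function(g, file = NULL) {
  validate_glyph(g)
  box <- glyph_bounding_box(g)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  lines <- c(sprintf(
    paste0("<svg xmlns=\"%s\" xmlns:parametric=\"%s\" parametric:type=\"%s\"",
           " parametric:defaults=\"%s\" viewBox=\"%s %s %s %s\">"),
    SVG_NS, PSVG_NS, esc(g$glyph_type), esc(defaults_attr_string(g$defaults)),
    format_coord(box[["xmin"]]), format_coord(box[["ymin"]]),
    format_coord(box[["xmax"]] - box[["xmin"]]),
    format_coord(box[["ymax"]] - box[["ymin"]])))
  emit_path <- function(id, d, pd, style) {
    attrs <- sprintf(" id=\"%s\" d=\"%s\"", esc(id), esc(d))
    if (!is.null(pd)) attrs <- paste0(attrs, sprintf(" parametric:d=\"%s\"", esc(pd)))
    st <- style_attr_string(style)
    if (nzchar(st)) attrs <- paste0(attrs, sprintf(" style=\"%s\"", esc(st)))
    paste0("  <path", attrs, "/>")
  }
  for (p in g$paths) {
    lines <- c(lines, emit_path(p$name, p$static_d, p$parametric_d, p$style))
  }
  hidden <- list(fill = "none", stroke = "none")
  bl_static <- evaluate_template(g$baseline_d, g$defaults)
  bb_static <- evaluate_template(g$bounding_box_d, g$defaults)
  lines <- c(lines,
             emit_path("baseline", bl_static,
                       if (grepl("\\{", g$baseline_d)) g$baseline_d else NULL, hidden),
             emit_path("bounding-box", bb_static,
                       if (grepl("\\{", g$bounding_box_d)) g$bounding_box_d else NULL, hidden),
             "</svg>")
  out <- paste(lines, collapse = "\n")
  xml2::read_xml(out) # assert well-formedness
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Load a directory of pSVG files as a glyph library
#'
#' @param directory Directory containing at least one `.svg`/`.psvg` file.
#' @param strict When `TRUE` (default) a file failing validation aborts the
#'   load with its filename; when `FALSE` such files are skipped with a
#'   warning.
#' @return A `glyph_library`: a named list of `glyph_definition`s keyed by
#'   glyph type.
#' @export
load_library <- function(directory, strict = TRUE) {
  files <- list.files(directory, pattern = "\\.p?svg$", full.names = TRUE)
  if (length(files) == 0L) {
    stop(sprintf("no pSVG files found in '%s'", directory), call. = FALSE)
  }
  glyphs <- list()
  for (f in files) {
    g <- tryCatch(read_glyph(f), error = function(e) {
      if (strict) {
        stop(sprintf("failed to load '%s': %s", basename(f), conditionMessage(e)),
             call. = FALSE)
      }
      warning(sprintf("skipping '%s': %s", basename(f), conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(g)) next
    if (g$glyph_type %in% names(glyphs)) {
      stop(sprintf("duplicate glyph type '%s' (second definition in '%s')",
                   g$glyph_type, basename(f)), call. = FALSE)
    }
    glyphs[[g$glyph_type]] <- g
  }
  if (length(glyphs) == 0L) stop("no valid glyph files loaded", call. = FALSE)
  structure(glyphs, class = "glyph_library")
}

#' @export
print.glyph_library <- function(x, ...) {
  cat(sprintf("<glyph library: %d glyph(s)> %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

as_glyph_library <- function(glyphs) {
  structure(stats::setNames(glyphs, vapply(glyphs, `[[`, character(1), "glyph_type")),
            class = "glyph_library")
}
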