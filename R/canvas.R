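#' An SVG drawing canvas
#'
#' The canvas is the drawing-surface contract used by the renderer: it
#' accepts filled/stroked paths and single-line text in call order
#' (painter's model) and finalizes to a well-formed SVG document. The
#' y-axis grows downward (SVG convention). It is a mutable object; draw
#' calls append to it.
#'
#' @param margin Padding, in canvas units, added around the drawn content
#'   when the document view box is computed.
#' @return An object of class `svg_canvas`.
#' @examples
#' cv <- svg_canvas()
#' canvas_path(cv, "M 0 0 L 10 0 L 5 -8 Z", style = list(fill = "orange"))
#' svg <- canvas_finalize(cv)
#' @export
svg_canvas <- function(margin = 5) {
  cv <- new.env(parent = emptyenv())
  cv$elements <- list()
  cv$bounds <- NULL
  cv$margin <- margin
  cv$path_count <- 0L
  cv$glyph_count <- 0L
  class(cv) <- "svg_canvas"
  cv
}

#' @export
print.svg_canvas <- function(x, ...) {
  cat(sprintf("<svg canvas: %d element(s)>\n", length(x$elements)))
  invisible(x)
}

#' Resolve a color specification
#'
#' Accepts `"none"`, hex triplets (`"#rgb"` or `"#rrggbb"`), or named
#' colors (the [grDevices::colors()] table, which covers the common CSS
#' names); names are canonicalized to hex. Unknown names are an error.
#' @param color A single color string.
#' @return A hex string, or `"none"`.
#' @export
resolve_color <- function(color) {
  if (is.null(color)) return(NULL)
  if (!is.character(color) || length(color) != 1L || is.na(color)) {
    stop("color must be a single string", call. = FALSE)
  }
  if (color == "none") return("none")
  if (grepl("^#([0-9a-fA-F]{3}|[0-9a-fA-F]{6})$", color)) return(tolower(color))
  if (!(color %in% grDevices::colors())) {
    stop(sprintf("unknown color name '%s'", color), call. = FALSE)
  }
  rgb <- grDevices::col2rgb(color)
  sprintf("#%02x%02x%02x", rgb[1], rgb[2], rgb[3])
}

resolve_style <- function(style) {
  style <- normalize_style(style)
  style$fill <- if (is.null(style$fill)) NULL else resolve_color(style$fill)
  style$stroke <- if (is.null(style$stroke)) NULL else resolve_color(style$stroke)
  style
}

#' Draw a path on a canvas
#'
#' @param canvas An [svg_canvas()].
#' @param d SVG path data (or a command list).
#' @param style Named list: `fill`, `stroke`, `stroke_width`, `opacity`.
#' @param id Optional `id` attribute for the emitted element.
#' @return The canvas, invisibly.
#' @export
canvas_path <- function(canvas, d, style = list(), id = NULL) {
  cmds <- if (is.character(d)) parse_path_data(d) else d
  dstr <- serialize_path_data(cmds)
  style <- resolve_style(style)
  canvas$elements[[length(canvas$elements) + 1L]] <- list(
    tag = "path", d = dstr, style = style, id = id)
  canvas$bounds <- bounds_union(canvas$bounds, path_bounds(cmds))
  canvas$path_count <- canvas$path_count + 1L
  invisible(canvas)
}

#' Draw a single line of text on a canvas
#'
#' @inheritParams canvas_path
#' @param x,y Text anchor position (canvas units).
#' @param text The label.
#' @param size Font size in canvas units.
#' @param color Text color.
#' @param anchor Horizontal anchoring: `"start"`, `"middle"` or `"end"`.
#' @export
canvas_text <- function(canvas, x, y, text, size = 8, color = "black",
                        anchor = c("middle", "start", "end"), id = NULL) {
  anchor <- match.arg(anchor)
  canvas$elements[[length(canvas$elements) + 1L]] <- list(
    tag = "text", x = x, y = y, text = as.character(text), size = size,
    color = resolve_color(color), anchor = anchor, id = id)
  # approximate extent for the view box; exact metrics are out of scope
  w <- 0.6 * size * nchar(text)
  x0 <- switch(anchor, start = x, middle = x - w / 2, end = x - w)
  canvas$bounds <- bounds_union(canvas$bounds, c(xmin = x0, ymin = y - size,
                                                 xmax = x0 + w, ymax = y))
  invisible(canvas)
}

#' Number of path elements drawn so far
#' @param canvas An [svg_canvas()].
#' @export
canvas_path_count <- function(canvas) canvas$path_count

#' Finalize a canvas to an SVG document
#'
#' The document's view box covers the union of everything drawn plus the
#' canvas margin; with no draw calls a small default view box is used.
#'
#' @param canvas An [svg_canvas()].
#' @param file Optional path to write the document to.
#' @return The SVG document as a single string.
#' @export
canvas_finalize <- function(canvas, file = NULL) {
  b <- canvas$bounds
  m <- canvas$margin
  vb <- if (is.null(b)) {
    c(0, 0, 10, 10)
  } else {
    c(b[["xmin"]] - m, b[["ymin"]] - m,
      b[["xmax"]] - b[["xmin"]] + 2 * m, b[["ymax"]] - b[["ymin"]] + 2 * m)
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  lines <- sprintf("<svg xmlns=\"%s\" viewBox=\"%s %s %s %s\" width=\"%s\" height=\"%s\">",
                   SVG_NS, format_coord(vb[1]), format_coord(vb[2]),
                   format_coord(vb[3]), format_coord(vb[4]),
                   format_coord(vb[3]), format_coord(vb[4]))
  for (el in canvas$elements) {
    idattr <- if (!is.null(el$id)) sprintf(" id=\"%s\"", esc(el$id)) else ""
    if (el$tag == "path") {
      st <- style_attr_string(el$style)
      lines <- c(lines, sprintf("  <path%s d=\"%s\"%s/>", idattr, esc(el$d),
                                if (nzchar(st)) sprintf(" style=\"%s\"", esc(st)) else ""))
    } else {
      lines <- c(lines, sprintf(
        "  <text%s x=\"%s\" y=\"%s\" font-size=\"%s\" fill=\"%s\" text-anchor=\"%s\">%s</text>",
        idattr, format_coord(el$x), format_coord(el$y), format_coord(el$size),
        el$color, el$anchor, esc(el$text)))
    }
  }
  out <- paste(c(lines, "</svg>"), collapse = "\n")
  xml2::read_xml(out) # assert well-formedness
  if (!is.null(file)) writeLines(out, file)
  out
}
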