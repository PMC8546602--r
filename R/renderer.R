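#' Overlay user parameters onto a glyph's defaults
#'
#' @param g A `glyph_definition`.
#' @param user Named numeric vector/list of parameter overrides (may be
#'   empty). Every name must be one of the glyph's parameters.
#' @return A full binding over exactly the glyph's parameter set.
#' @export
resolve_parameters <- function(g, user = numeric()) {
  user <- as_param_binding(user)
  unknown <- setdiff(names(user), names(g$defaults))
  if (length(unknown)) {
    stop(sprintf("unknown parameter(s) %s for glyph '%s' (valid: %s)",
                 paste(sprintf("'%s'", unknown), collapse = ", "), g$glyph_type,
                 if (length(g$defaults)) paste(names(g$defaults), collapse = ", ")
                 else "none"), call. = FALSE)
  }
  out <- g$defaults
  out[names(user)] <- user
  out
}

merge_styles <- function(default, override) {
  override <- normalize_style(override)
  out <- default
  out[names(override)] <- override
  out
}

#' Draw one glyph at an anchor, returning the composition contract
#'
#' The glyph's templates are evaluated at the resolved parameters
#' (defaults overlaid by `user_parameters`), the geometry is positioned so
#' the start of the glyph's baseline coincides with `anchor`, and each
#' visible path is painted with its default style overlaid by `user_style`.
#' Reverse orientation rotates the evaluated geometry 180 degrees about the
#' midpoint of its own baseline before anchoring (the SBOL Visual
#' reverse-strand convention), which flips the glyph below the baseline but
#' preserves the baseline extent — so composition is orientation-blind.
#'
#' The baseline and bounding-box marker paths are never painted. Painted
#' paths carry `id` attributes `"<glyph_type>.<path_name>.<instance>"`.
#'
#' @param lib A `glyph_library` (or a single `glyph_definition`).
#' @param glyph_type Glyph to draw (ignored when `lib` is a definition).
#' @param anchor Baseline start point `c(x, y)` in canvas units.
#' @param orientation `"forward"` or `"reverse"`.
#' @param user_parameters Geometry overrides (see [resolve_parameters()]).
#' @param user_style Named list: path name -> style record (`fill`,
#'   `stroke`, `stroke_width`, `opacity`). Names must exist in the glyph.
#' @param canvas An [svg_canvas()] to paint on, or `NULL` to only compute
#'   the contract (used by layout prediction).
#' @return A `render_result`: list with `bounds` (named numeric, the
#'   glyph's declared bounding box after transformation), `baseline_start`
#'   (echo of `anchor`) and `baseline_end` (where the next glyph starts).
#' @examples
#' lib <- make_fixture_library()
#' cv <- svg_canvas()
#' res <- draw_glyph(lib, "CDS", anchor = c(100, 50), canvas = cv)
#' res$baseline_end
#' @export
draw_glyph <- function(lib, glyph_type = NULL, anchor = c(0, 0),
                       orientation = c("forward", "reverse"),
                       user_parameters = numeric(), user_style = list(),
                       canvas = NULL) {
  orientation <- match.arg(orientation)
  g <- if (inherits(lib, "glyph_definition")) {
    lib
  } else {
    if (is.null(glyph_type) || !(glyph_type %in% names(lib))) {
      stop(sprintf("unknown glyph type '%s' (library has: %s)",
                   glyph_type %||% "<missing>", paste(names(lib), collapse = ", ")),
           call. = FALSE)
    }
    lib[[glyph_type]]
  }
  path_names <- vapply(g$paths, `[[`, character(1), "name")
  bad_style <- setdiff(names(user_style), path_names)
  if (length(bad_style)) {
    stop(sprintf("user_style names %s do not match any path of glyph '%s' (paths: %s)",
                 paste(sprintf("'%s'", bad_style), collapse = ", "), g$glyph_type,
                 paste(path_names, collapse = ", ")), call. = FALSE)
  }
  binding <- resolve_parameters(g, user_parameters)
  bl <- glyph_baseline(g, binding)
  box <- glyph_bounding_box(g, binding)

  tf <- transform_identity()
  if (orientation == "reverse") {
    mid <- (bl$start + bl$end) / 2
    tf <- transform_rotate(pi, center = mid)
  }
  # anchor the left baseline endpoint (rotation swaps start and end)
  bl_pts <- list(transform_point(tf, bl$start), transform_point(tf, bl$end))
  left <- if (bl_pts[[1]][1] <= bl_pts[[2]][1]) bl_pts[[1]] else bl_pts[[2]]
  tf <- transform_compose(transform_translate(anchor[1] - left[1], anchor[2] - left[2]), tf)

  span <- abs(bl$end[1] - bl$start[1])
  box_cmds <- apply_transform(
    parse_path_data(evaluate_template(g$bounding_box_d, binding)), tf)
  bounds <- path_bounds(box_cmds)

  if (!is.null(canvas)) {
    idx <- canvas$glyph_count
    canvas$glyph_count <- idx + 1L
    for (p in g$paths) {
      d <- if (is.null(p$parametric_d)) p$static_d else evaluate_template(p$parametric_d, binding)
      cmds <- apply_transform(parse_path_data(d), tf)
      canvas_path(canvas, cmds,
                  style = merge_styles(p$style, user_style[[p$name]]),
                  id = sprintf("%s.%s.%d", g$glyph_type, p$name, idx))
    }
  }
  structure(list(bounds = bounds,
                 baseline_start = c(anchor[1], anchor[2]),
                 baseline_end = c(anchor[1] + span, anchor[2])),
            class = "render_result")
}

#' @export
print.render_result <- function(x, ...) {
  cat(sprintf("<render result: baseline (%g,%g) -> (%g,%g); bounds [%g,%g] x [%g,%g]>\n",
              x$baseline_start[1], x$baseline_start[2],
              x$baseline_end[1], x$baseline_end[2],
              x$bounds[["xmin"]], x$bounds[["xmax"]],
              x$bounds[["ymin"]], x$bounds[["ymax"]]))
  invisible(x)
}
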