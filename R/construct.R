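#' Build a parts table
#'
#' A genetic construct is an ordered table of parts: one row per part, with
#' the glyph type, strand orientation, optional label, optional width hint
#' (canvas units, mapped onto the glyph's `width` parameter) and per-part
#' geometry/style overrides. Rows combine with [dplyr::bind_rows()] or the
#' [parts()] helper, so designs compose pipe-style.
#'
#' @param glyph_type SBOL Visual glyph type, resolvable in the active
#'   library.
#' @param orientation `"forward"` or `"reverse"`.
#' @param user_parameters Named numeric overrides for glyph parameters.
#' @param user_style Named list: path name -> style record.
#' @param label Optional text drawn beneath the part.
#' @param width_hint Optional width in canvas units (> 0); overrides the
#'   glyph's `width` parameter.
#' @return A one-row tibble with class-stable list-columns.
#' @examples
#' design <- parts(part("Promoter"), part("RBS"), part("CDS"), part("Terminator"))
#' @export
part <- function(glyph_type, orientation = c("forward", "reverse"),
                 user_parameters = numeric(), user_style = list(),
                 label = NA_character_, width_hint = NA_real_) {
  orientation <- match.arg(orientation)
  if (!is.na(width_hint) && width_hint <= 0) {
    stop("width_hint must be positive", call. = FALSE)
  }
  tibble::tibble(glyph_type = glyph_type, orientation = orientation,
                 label = label, width_hint = as.numeric(width_hint),
                 user_parameters = list(as_param_binding(user_parameters)),
                 user_style = list(user_style))
}

#' @rdname part
#' @param ... One-row part tibbles (or multi-row parts tables) to combine
#'   in order.
#' @export
parts <- function(...) dplyr::bind_rows(...)

empty_parts <- function() {
  tibble::tibble(glyph_type = character(0), orientation = character(0),
                 label = character(0), width_hint = numeric(0),
                 user_parameters = list(), user_style = list())
}

#' Build an interactions table
#'
#' A regulatory interaction is an arc drawn above the construct from one
#' part to another. Part indices are 0-based, matching the command-line
#' shorthand notation (`"0//2//in//red"` runs from the first part to the
#' third).
#'
#' @param from,to 0-based part indices; must differ.
#' @param kind `"inhibition"` (bar terminal), `"control"` (open diamond) or
#'   `"stimulation"` (open arrowhead).
#' @param color Arc color.
#' @return A one-row tibble; combine with [dplyr::bind_rows()].
#' @export
interaction <- function(from, to, kind = c("inhibition", "control", "stimulation"),
                        color = "black") {
  kind <- match.arg(kind)
  from <- as.integer(from)
  to <- as.integer(to)
  if (is.na(from) || is.na(to) || from < 0L || to < 0L) {
    stop("interaction indices must be nonnegative integers", call. = FALSE)
  }
  if (from == to) stop("an interaction must span two distinct parts", call. = FALSE)
  tibble::tibble(from = from, to = to, kind = kind, color = color)
}

empty_interactions <- function() {
  tibble::tibble(from = integer(0), to = integer(0), kind = character(0),
                 color = character(0))
}

#' Assemble a construct specification
#'
#' @param parts Parts table from [part()]/[parts()] (may be empty).
#' @param interactions Interactions table from [interaction()], or `NULL`.
#' @param part_spacing Horizontal gap between consecutive parts (units,
#'   >= 0).
#' @param start Anchor of the first part's baseline.
#' @param max_line_width When set (> 0), rows wrap greedily at this width.
#' @param line_spacing Vertical distance between row baselines.
#' @param base_clearance Height of the lowest interaction arc above the
#'   baseline; default `NULL` means 1.2 x the tallest glyph in the arc's
#'   span.
#' @param level_step Extra clearance per arc stacking level.
#' @param backbone Draw a continuous backbone line under each row.
#' @return An object of class `construct_spec`.
#' @export
construct_spec <- function(parts = empty_parts(), interactions = NULL,
                           part_spacing = 5, start = c(0, 0),
                           max_line_width = NULL, line_spacing = 50,
                           base_clearance = NULL, level_step = 6,
                           backbone = TRUE) {
  if (part_spacing < 0) stop("part_spacing must be nonnegative", call. = FALSE)
  if (!is.null(max_line_width) && max_line_width <= 0) {
    stop("max_line_width must be positive", call. = FALSE)
  }
  if (line_spacing < 0) stop("line_spacing must be nonnegative", call. = FALSE)
  if (is.null(interactions)) interactions <- empty_interactions()
  n <- nrow(parts)
  if (nrow(interactions)) {
    bad <- interactions$from >= n | interactions$to >= n |
      interactions$from < 0 | interactions$to < 0
    if (any(bad)) {
      stop(sprintf("interaction index out of range for %d part(s): %s", n,
                   paste(sprintf("%d->%d", interactions$from[bad],
                                 interactions$to[bad]), collapse = ", ")),
           call. = FALSE)
    }
    if (any(interactions$from == interactions$to)) {
      stop("an interaction must span two distinct parts", call. = FALSE)
    }
  }
  structure(list(parts = parts, interactions = interactions,
                 part_spacing = part_spacing, start = start,
                 max_line_width = max_line_width, line_spacing = line_spacing,
                 base_clearance = base_clearance, level_step = level_step,
                 backbone = backbone),
            class = "construct_spec")
}

#' @export
print.construct_spec <- function(x, ...) {
  cat(sprintf("<construct: %d part(s), %d interaction(s), spacing %g%s>\n",
              nrow(x$parts), nrow(x$interactions), x$part_spacing,
              if (!is.null(x$max_line_width)) {
                sprintf(", wrap at %g", x$max_line_width)
              } else {
                ""
              }))
  invisible(x)
}

lookup_glyph <- function(lib, glyph_type) {
  g <- lib[[glyph_type]]
  if (is.null(g)) {
    stop(sprintf("unknown glyph type '%s' (library has: %s)", glyph_type,
                 paste(names(lib), collapse = ", ")), call. = FALSE)
  }
  g
}

part_binding <- function(prt, lib) {
  g <- lookup_glyph(lib, prt$glyph_type)
  user <- prt$user_parameters[[1]]
  if (!is.na(prt$width_hint)) {
    if (!("width" %in% names(g$defaults))) {
      stop(sprintf("width_hint given but glyph '%s' has no 'width' parameter",
                   g$glyph_type), call. = FALSE)
    }
    user[["width"]] <- prt$width_hint
  }
  resolve_parameters(g, user)
}

part_span <- function(prt, lib) {
  g <- lookup_glyph(lib, prt$glyph_type)
  bl <- glyph_baseline(g, part_binding(prt, lib))
  abs(bl$end[1] - bl$start[1])
}

#' Lay parts out along one baseline
#'
#' Computes each part's anchor and predicted composition contract without
#' drawing: part 1 is anchored at `spec$start`, and each next anchor is the
#' previous baseline end shifted right by `part_spacing`. No wrapping is
#' applied here.
#'
#' @param spec A `construct_spec`.
#' @param lib A `glyph_library`.
#' @return A tibble with one row per part: `part_index` (1-based),
#'   `glyph_type`, `orientation`, `anchor_x`, `anchor_y`, `baseline_end_x`,
#'   and bounds columns `xmin`, `ymin`, `xmax`, `ymax`.
#' @export
layout_parts <- function(spec, lib) {
  n <- nrow(spec$parts)
  out <- vector("list", n)
  x <- spec$start[1]
  y <- spec$start[2]
  for (i in seq_len(n)) {
    prt <- spec$parts[i, ]
    res <- draw_glyph(lib, prt$glyph_type, anchor = c(x, y),
                      orientation = prt$orientation,
                      user_parameters = part_binding(prt, lib),
                      canvas = NULL)
    out[[i]] <- tibble::tibble(
      part_index = i, glyph_type = prt$glyph_type, orientation = prt$orientation,
      anchor_x = x, anchor_y = y, baseline_end_x = res$baseline_end[1],
      xmin = res$bounds[["xmin"]], ymin = res$bounds[["ymin"]],
      xmax = res$bounds[["xmax"]], ymax = res$bounds[["ymax"]])
    x <- res$baseline_end[1] + spec$part_spacing
  }
  if (n == 0L) {
    return(tibble::tibble(part_index = integer(0), glyph_type = character(0),
                          orientation = character(0), anchor_x = numeric(0),
                          anchor_y = numeric(0), baseline_end_x = numeric(0),
                          xmin = numeric(0), ymin = numeric(0),
                          xmax = numeric(0), ymax = numeric(0)))
  }
  dplyr::bind_rows(out)
}

#' Wrap a construct's parts into rows
#'
#' Greedy left-to-right fill: a part opens a new row when adding it (plus
#' the inter-part spacing) would exceed `max_line_width` — unless it would
#' be the row's first part, in which case the oversized part gets the row
#' to itself. Order is preserved and every part lands in exactly one row.
#'
#' @inheritParams layout_parts
#' @return A list of integer vectors of 1-based part indices, one per row.
#' @export
wrap_lines <- function(spec, lib) {
  if (is.null(spec$max_line_width)) {
    stop("wrap_lines requires spec$max_line_width", call. = FALSE)
  }
  n <- nrow(spec$parts)
  if (n == 0L) return(list())
  spans <- vapply(seq_len(n), function(i) part_span(spec$parts[i, ], lib), numeric(1))
  rows <- list()
  cur <- integer(0)
  w <- 0
  for (i in seq_len(n)) {
    cost <- if (length(cur)) spec$part_spacing + spans[i] else spans[i]
    if (length(cur) && w + cost > spec$max_line_width) {
      rows[[length(rows) + 1L]] <- cur
      cur <- integer(0)
      w <- 0
      cost <- spans[i]
    }
    cur <- c(cur, i)
    w <- w + cost
  }
  rows[[length(rows) + 1L]] <- cur
  rows
}

# arc stacking levels: an arc sits one level above every earlier arc whose
# part-index span overlaps its own (input order is the routing order)
arc_levels <- function(interactions) {
  n <- nrow(interactions)
  lev <- integer(n)
  if (n == 0L) return(lev)
  lo <- pmin(interactions$from, interactions$to)
  hi <- pmax(interactions$from, interactions$to)
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    overlap <- prev[lo[prev] <= hi[i] & lo[i] <= hi[prev]]
    lev[i] <- length(overlap)
  }
  lev
}

#' Route one interaction arc over a laid-out row
#'
#' The arc runs from above the source part's bounds center to above the
#' target part's bounds center at a clearance of
#' `base_clearance + level * level_step` over the row baseline, and ends in
#' a kind-specific terminal: a perpendicular bar (inhibition), an open
#' diamond (control) or an open arrowhead (stimulation).
#'
#' @param inter One-row interactions tibble (see [interaction()]).
#' @param layout Row layout from [layout_parts()].
#' @param level Stacking level (0 = lowest; see [construct_spec()]).
#' @param base_clearance,level_step Clearance constants; `NULL` base
#'   clearance means 1.2 x the tallest glyph in the span.
#' @return List with `arc` (command list), `terminal` (command list),
#'   `terminal_name`, `color`, and `bounds`.
#' @export
route_interaction <- function(inter, layout, level = 0,
                              base_clearance = NULL, level_step = 6) {
  if (inter$from >= nrow(layout) || inter$to >= nrow(layout)) {
    stop(sprintf("interaction %d->%d out of range for %d laid-out part(s)",
                 inter$from, inter$to, nrow(layout)), call. = FALSE)
  }
  src <- layout[inter$from + 1L, ]
  dst <- layout[inter$to + 1L, ]
  span <- layout[seq(min(inter$from, inter$to) + 1L, max(inter$from, inter$to) + 1L), ]
  base_y <- src$anchor_y
  if (is.null(base_clearance)) {
    base_clearance <- 1.2 * max(base_y - span$ymin, 0)
  }
  y_arc <- base_y - (base_clearance + level * level_step)
  gap <- 0 # stubs meet the part's top edge so the apex sits at the clearance
  xs <- (src$xmin + src$xmax) / 2
  xt <- (dst$xmin + dst$xmax) / 2
  ys <- src$ymin - gap
  yt <- dst$ymin - gap
  arc <- parse_path_data(sprintf("M %s %s L %s %s L %s %s L %s %s",
                                 format_coord(xs), format_coord(ys),
                                 format_coord(xs), format_coord(y_arc),
                                 format_coord(xt), format_coord(y_arc),
                                 format_coord(xt), format_coord(yt)))
  terminal <- switch(inter$kind,
    inhibition = parse_path_data(sprintf("M %s %s L %s %s",
                                         format_coord(xt - 3), format_coord(yt),
                                         format_coord(xt + 3), format_coord(yt))),
    control = parse_path_data(sprintf("M %s %s L %s %s L %s %s L %s %s Z",
                                      format_coord(xt), format_coord(yt),
                                      format_coord(xt + 2.5), format_coord(yt + 2.5),
                                      format_coord(xt), format_coord(yt + 5),
                                      format_coord(xt - 2.5), format_coord(yt + 2.5))),
    stimulation = parse_path_data(sprintf("M %s %s L %s %s L %s %s",
                                          format_coord(xt - 3), format_coord(yt),
                                          format_coord(xt), format_coord(yt + 4),
                                          format_coord(xt + 3), format_coord(yt))))
  terminal_name <- c(inhibition = "bar", control = "diamond",
                     stimulation = "arrowhead")[[inter$kind]]
  list(arc = arc, terminal = terminal, terminal_name = terminal_name,
       color = inter$color,
       bounds = bounds_union(path_bounds(arc), path_bounds(terminal)))
}

#' Render a whole construct with one call
#'
#' Wraps the parts into rows when `max_line_width` is set, lays each row
#' out at `start.y + row * line_spacing`, draws a continuous backbone line
#' along each row's baseline, then the parts and labels, then the
#' interaction arcs. An interaction whose parts land on different rows is
#' drawn within the source part's row and truncated at the row edge
#' (without a terminal decoration).
#'
#' @inheritParams layout_parts
#' @param canvas An [svg_canvas()].
#' @return Union bounds of everything drawn (named numeric), or a
#'   zero-extent bounds at `spec$start` for an empty construct.
#' @examples
#' lib <- make_fixture_library()
#' design <- parse_design_string("p r c t")
#' spec <- construct_spec(design, interaction(0, 2, "inhibition", "red"))
#' cv <- svg_canvas()
#' render_construct(spec, lib, cv)
#' svg <- canvas_finalize(cv)
#' @export
render_construct <- function(spec, lib, canvas) {
  n <- nrow(spec$parts)
  if (n == 0L) {
    return(c(xmin = spec$start[1], ymin = spec$start[2],
             xmax = spec$start[1], ymax = spec$start[2]))
  }
  rows <- if (!is.null(spec$max_line_width)) {
    wrap_lines(spec, lib)
  } else {
    list(seq_len(n))
  }
  row_of_part <- integer(n)
  for (r in seq_along(rows)) row_of_part[rows[[r]]] <- r

  total <- NULL
  layouts <- vector("list", length(rows))
  # backbone + parts, row by row
  for (r in seq_along(rows)) {
    idx <- rows[[r]]
    row_start <- c(spec$start[1], spec$start[2] + (r - 1) * spec$line_spacing)
    row_spec <- construct_spec(spec$parts[idx, , drop = FALSE],
                               part_spacing = spec$part_spacing,
                               start = row_start)
    lay <- layout_parts(row_spec, lib)
    layouts[[r]] <- lay
    if (spec$backbone) {
      x0 <- lay$anchor_x[1]
      x1 <- lay$baseline_end_x[nrow(lay)]
      canvas_path(canvas,
                  sprintf("M %s %s L %s %s", format_coord(x0), format_coord(row_start[2]),
                          format_coord(x1), format_coord(row_start[2])),
                  style = list(stroke = "black", stroke_width = 1.5, fill = "none"),
                  id = sprintf("backbone.%d", r - 1L))
      total <- bounds_union(total, c(xmin = x0, ymin = row_start[2],
                                     xmax = x1, ymax = row_start[2]))
    }
    for (k in seq_along(idx)) {
      prt <- spec$parts[idx[k], ]
      res <- draw_glyph(lib, prt$glyph_type,
                        anchor = c(lay$anchor_x[k], lay$anchor_y[k]),
                        orientation = prt$orientation,
                        user_parameters = part_binding(prt, lib),
                        user_style = prt$user_style[[1]],
                        canvas = canvas)
      total <- bounds_union(total, res$bounds)
      if (!is.na(prt$label)) {
        cx <- (res$bounds[["xmin"]] + res$bounds[["xmax"]]) / 2
        canvas_text(canvas, cx, lay$anchor_y[k] + 14, prt$label,
                    id = sprintf("label.%d", idx[k] - 1L))
      }
    }
  }
  # interaction arcs, per source row, stacked deterministically in input order
  if (nrow(spec$interactions)) {
    lev <- arc_levels(spec$interactions)
    for (i in seq_len(nrow(spec$interactions))) {
      inter <- spec$interactions[i, ]
      r_src <- row_of_part[inter$from + 1L]
      r_dst <- row_of_part[inter$to + 1L]
      lay <- layouts[[r_src]]
      arc_style <- list(stroke = inter$color, fill = "none", stroke_width = 1)
      if (r_src == r_dst) {
        offset <- min(rows[[r_src]]) - 1L
        local <- inter
        local$from <- inter$from - offset
        local$to <- inter$to - offset
        routed <- route_interaction(local, lay, level = lev[i],
                                    base_clearance = spec$base_clearance,
                                    level_step = spec$level_step)
        canvas_path(canvas, routed$arc, style = arc_style,
                    id = sprintf("interaction.%d.arc", i - 1L))
        term_style <- if (inter$kind == "inhibition") {
          arc_style
        } else {
          list(stroke = inter$color, fill = "white", stroke_width = 1)
        }
        canvas_path(canvas, routed$terminal, style = term_style,
                    id = sprintf("interaction.%d.%s", i - 1L, routed$terminal_name))
        total <- bounds_union(total, routed$bounds)
      } else {
        # cross-row interaction: truncate at the source row's edge
        src <- lay[inter$from + 1L - (min(rows[[r_src]]) - 1L), ]
        base_y <- src$anchor_y
        clearance <- spec$base_clearance %||% (1.2 * max(base_y - lay$ymin, 0))
        y_arc <- base_y - (clearance + lev[i] * spec$level_step)
        xs <- (src$xmin + src$xmax) / 2
        edge_x <- max(lay$baseline_end_x) + spec$part_spacing
        arc <- sprintf("M %s %s L %s %s L %s %s",
                       format_coord(xs), format_coord(src$ymin),
                       format_coord(xs), format_coord(y_arc),
                       format_coord(edge_x), format_coord(y_arc))
        canvas_path(canvas, arc, style = arc_style,
                    id = sprintf("interaction.%d.arc", i - 1L))
        total <- bounds_union(total, path_bounds(arc))
      }
    }
  }
  total
}
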