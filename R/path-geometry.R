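#' Parse SVG path data into a command list
#'
#' Supports the absolute opcodes `M`, `L`, `C`, `Q`, `A`, `Z`; lowercase
#' (relative) forms are accepted and normalized to absolute coordinates
#' during parsing. Implicit command repetition (`"L 1 2 3 4"`) follows the
#' SVG rule, with a repeated `M` continuing as `L`. Arguments may be
#' separated by whitespace or commas.
#'
#' @param d A single non-empty SVG path-data string.
#' @return A list of commands, each `list(op = <"M"|"L"|"C"|"Q"|"A"|"Z">,
#'   args = <numeric>)`, all absolute.
#' @export
parse_path_data <- function(d) {
  if (!is.character(d) || length(d) != 1L || is.na(d) || !nzchar(trimws(d))) {
    stop("path data must be a single non-empty string", call. = FALSE)
  }
  # split opcodes from numbers; commas are argument separators
  spaced <- gsub(",", " ", d, fixed = TRUE)
  spaced <- gsub("([A-Za-z])", " \\1 ", spaced)
  toks <- strsplit(trimws(spaced), "[[:space:]]+")[[1]]
  arity <- c(M = 2L, L = 2L, C = 6L, Q = 4L, A = 7L, Z = 0L)

  cmds <- list()
  cp <- c(NA_real_, NA_real_)     # current point
  start <- c(NA_real_, NA_real_)  # current subpath start (for Z and after-z)
  i <- 1L
  n <- length(toks)
  last_op <- NULL # absolute opcode of previous command, for implicit repeats
  last_rel <- FALSE
  first <- TRUE
  while (i <= n) {
    tk <- toks[i]
    if (grepl("^[A-Za-z]$", tk)) {
      op_abs <- toupper(tk)
      rel <- tk != op_abs
      if (!(op_abs %in% names(arity))) {
        stop(sprintf("path parse error at token %d: unsupported opcode '%s'", i, tk),
             call. = FALSE)
      }
      i <- i + 1L
    } else {
      # implicit repeat of the previous opcode; M repeats as L
      if (is.null(last_op)) {
        stop(sprintf("path parse error at token %d: expected an opcode, got '%s'", i, tk),
             call. = FALSE)
      }
      op_abs <- if (last_op == "M") "L" else last_op
      rel <- last_rel
      if (op_abs == "Z") {
        stop(sprintf("path parse error at token %d: numbers after Z", i), call. = FALSE)
      }
    }
    if (first && op_abs != "M") {
      stop("path parse error: path data must start with an M command", call. = FALSE)
    }
    k <- arity[[op_abs]]
    if (k > 0L) {
      if (i + k - 1L > n) {
        stop(sprintf("path parse error at token %d: '%s' needs %d numbers, found %d",
                     i, op_abs, k, n - i + 1L), call. = FALSE)
      }
      args <- suppressWarnings(as.numeric(toks[i:(i + k - 1L)]))
      if (any(is.na(args))) {
        bad <- i + which(is.na(args))[1] - 1L
        stop(sprintf("path parse error at token %d: '%s' is not a number", bad, toks[bad]),
             call. = FALSE)
      }
      i <- i + k
    } else {
      args <- numeric(0)
    }
    if (rel && op_abs != "Z") {
      if (op_abs %in% c("M", "L")) {
        if (!first) args <- args + cp else rel <- FALSE
      } else if (op_abs == "C") {
        args <- args + rep(cp, 3)
      } else if (op_abs == "Q") {
        args <- args + rep(cp, 2)
      } else if (op_abs == "A") {
        args[6:7] <- args[6:7] + cp
      }
    }
    if (op_abs == "M") {
      cp <- args
      start <- args
    } else if (op_abs == "Z") {
      cp <- start
    } else {
      na <- length(args)
      cp <- args[(na - 1L):na]
    }
    cmds[[length(cmds) + 1L]] <- list(op = op_abs, args = args)
    last_op <- op_abs
    last_rel <- rel
    first <- FALSE
  }
  if (length(cmds) == 0L) stop("path parse error: no commands", call. = FALSE)
  cmds
}

#' Serialize a command list back to SVG path data
#'
#' Numbers are written with up to 9 significant digits, trailing zeros
#' trimmed, space-separated (the arc flags as integers).
#' @param commands A command list as returned by [parse_path_data()].
#' @return A single path-data string.
#' @export
serialize_path_data <- function(commands) {
  vapply(commands, function(cmd) {
    if (length(cmd$args) == 0L) return(cmd$op)
    paste(cmd$op, paste(vapply(cmd$args, format_coord, character(1)), collapse = " "))
  }, character(1)) |> paste(collapse = " ")
}

format_coord <- function(x) {
  if (!is.finite(x)) stop("cannot serialize a non-finite coordinate", call. = FALSE)
  v <- signif(x, 9)
  if (v == 0) v <- 0 # normalize -0
  format(v, digits = 15, scientific = FALSE, trim = TRUE)
}

#' Evaluate a parametric path template to concrete path data
#'
#' A template is SVG path data in which any coordinate may be written as a
#' `{expression}` over named parameters, e.g.
#' `"M 0 0 L {width - arrowhead_width} {-height/2}"`. Each braced expression
#' is evaluated against `binding` and replaced by the numeric result; the
#' result is valid SVG path data.
#'
#' @param template Path-data template string.
#' @param binding Parameter binding (see [as_param_binding()]).
#' @return Concrete path-data string.
#' @export
evaluate_template <- function(template, binding = numeric()) {
  binding <- as_param_binding(binding)
  m <- gregexpr("\\{[^{}]*\\}", template)[[1]]
  out <- template
  if (m[1] != -1L) {
    pieces <- regmatches(template, gregexpr("\\{[^{}]*\\}", template))[[1]]
    values <- vapply(pieces, function(p) {
      inner <- substr(p, 2, nchar(p) - 1L)
      format_coord(evaluate_expression(inner, binding))
    }, character(1), USE.NAMES = FALSE)
    regmatches(out, gregexpr("\\{[^{}]*\\}", out)) <- list(values)
  }
  if (grepl("[{}]", out)) {
    stop(sprintf("malformed braces in path template: \"%s\"", template), call. = FALSE)
  }
  out
}

#' Parameters referenced anywhere in a path template
#' @inheritParams evaluate_template
#' @return Character vector of distinct parameter names.
#' @export
template_parameters <- function(template) {
  pieces <- regmatches(template, gregexpr("\\{[^{}]*\\}", template))[[1]]
  if (length(pieces) == 0L) return(character(0))
  unique(unlist(lapply(pieces, function(p) {
    expression_parameters(substr(p, 2, nchar(p) - 1L))
  })))
}

#' Tight axis-aligned bounds of path geometry
#'
#' Line segments contribute their endpoints; cubic and quadratic Beziers
#' are bounded exactly via derivative extrema; elliptical arcs are first
#' converted to cubic segments of at most pi/8 radians each, keeping the
#' approximation error far below 1e-6 of the curve span.
#'
#' @param commands Command list from [parse_path_data()] (or a path-data
#'   string, parsed first).
#' @return Named numeric `c(xmin, ymin, xmax, ymax)`.
#' @export
path_bounds <- function(commands) {
  if (is.character(commands)) commands <- parse_path_data(commands)
  if (length(commands) == 0L) stop("cannot bound an empty command list", call. = FALSE)
  xs <- numeric(0)
  ys <- numeric(0)
  cp <- c(NA_real_, NA_real_)
  start <- c(NA_real_, NA_real_)
  add_pt <- function(p) {
    xs[[length(xs) + 1L]] <<- p[1]
    ys[[length(ys) + 1L]] <<- p[2]
  }
  for (cmd in commands) {
    a <- cmd$args
    switch(cmd$op,
      M = {
        cp <- a
        start <- a
        add_pt(a)
      },
      L = {
        add_pt(a)
        cp <- a
      },
      C = {
        ext <- cubic_extrema(cp, a[1:2], a[3:4], a[5:6])
        xs <- c(xs, ext$x)
        ys <- c(ys, ext$y)
        cp <- a[5:6]
      },
      Q = {
        # elevate to cubic: exact
        c1 <- cp + 2 / 3 * (a[1:2] - cp)
        c2 <- a[3:4] + 2 / 3 * (a[1:2] - a[3:4])
        ext <- cubic_extrema(cp, c1, c2, a[3:4])
        xs <- c(xs, ext$x)
        ys <- c(ys, ext$y)
        cp <- a[3:4]
      },
      A = {
        segs <- arc_to_cubics(cp, a)
        for (s in segs) {
          ext <- cubic_extrema(s$p0, s$p1, s$p2, s$p3)
          xs <- c(xs, ext$x)
          ys <- c(ys, ext$y)
        }
        cp <- a[6:7]
      },
      Z = {
        cp <- start
      })
  }
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

bounds_union <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  c(xmin = min(a[["xmin"]], b[["xmin"]]), ymin = min(a[["ymin"]], b[["ymin"]]),
    xmax = max(a[["xmax"]], b[["xmax"]]), ymax = max(a[["ymax"]], b[["ymax"]]))
}

# per-axis extrema of one cubic segment: endpoints + interior stationary points
cubic_extrema <- function(p0, p1, p2, p3) {
  axis_vals <- function(k) {
    b <- c(p0[k], p1[k], p2[k], p3[k])
    # B'(t) coefficients (quadratic in t)
    ca <- 3 * (-b[1] + 3 * b[2] - 3 * b[3] + b[4])
    cb <- 6 * (b[1] - 2 * b[2] + b[3])
    cc <- 3 * (b[2] - b[1])
    ts <- numeric(0)
    if (abs(ca) < 1e-12) {
      if (abs(cb) > 1e-12) ts <- -cc / cb
    } else {
      disc <- cb * cb - 4 * ca * cc
      if (disc >= 0) {
        sq <- sqrt(disc)
        ts <- c((-cb + sq) / (2 * ca), (-cb - sq) / (2 * ca))
      }
    }
    ts <- ts[ts > 0 & ts < 1]
    vals <- c(b[1], b[4])
    if (length(ts)) {
      mt <- 1 - ts
      vals <- c(vals, mt^3 * b[1] + 3 * mt^2 * ts * b[2] + 3 * mt * ts^2 * b[3] + ts^3 * b[4])
    }
    vals
  }
  list(x = axis_vals(1), y = axis_vals(2))
}

# SVG endpoint-parameterized arc -> center parameterization
arc_center_form <- function(cp, a) {
  rx <- abs(a[1]); ry <- abs(a[2])
  phi <- a[3] * pi / 180
  laf <- a[4] != 0; sf <- a[5] != 0
  p2 <- a[6:7]
  if (rx == 0 || ry == 0 || all(abs(cp - p2) < 1e-300)) return(NULL)
  cphi <- cos(phi); sphi <- sin(phi)
  dx2 <- (cp[1] - p2[1]) / 2; dy2 <- (cp[2] - p2[2]) / 2
  x1p <- cphi * dx2 + sphi * dy2
  y1p <- -sphi * dx2 + cphi * dy2
  lam <- x1p^2 / rx^2 + y1p^2 / ry^2
  if (lam > 1) {
    s <- sqrt(lam)
    rx <- rx * s; ry <- ry * s
  }
  num <- rx^2 * ry^2 - rx^2 * y1p^2 - ry^2 * x1p^2
  den <- rx^2 * y1p^2 + ry^2 * x1p^2
  co <- sqrt(max(0, num / den))
  if (laf == sf) co <- -co
  cxp <- co * rx * y1p / ry
  cyp <- -co * ry * x1p / rx
  cx <- cphi * cxp - sphi * cyp + (cp[1] + p2[1]) / 2
  cy <- sphi * cxp + cphi * cyp + (cp[2] + p2[2]) / 2
  ang <- function(ux, uy, vx, vy) {
    d <- atan2(vy, vx) - atan2(uy, ux)
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    d
  }
  th1 <- atan2((y1p - cyp) / ry, (x1p - cxp) / rx)
  dth <- ang((x1p - cxp) / rx, (y1p - cyp) / ry,
             (-x1p - cxp) / rx, (-y1p - cyp) / ry)
  if (!sf && dth > 0) dth <- dth - 2 * pi
  if (sf && dth < 0) dth <- dth + 2 * pi
  list(cx = cx, cy = cy, rx = rx, ry = ry, phi = phi, theta1 = th1, dtheta = dth,
       p1 = cp, p2 = p2)
}

# approximate an arc by cubic segments of at most pi/8 each
arc_to_cubics <- function(cp, a) {
  cf <- arc_center_form(cp, a)
  if (is.null(cf)) {
    return(list(list(p0 = cp, p1 = cp, p2 = a[6:7], p3 = a[6:7])))
  }
  nseg <- max(1L, ceiling(abs(cf$dtheta) / (pi / 8)))
  dth <- cf$dtheta / nseg
  cphi <- cos(cf$phi); sphi <- sin(cf$phi)
  epoint <- function(th) {
    x <- cf$rx * cos(th); y <- cf$ry * sin(th)
    c(cf$cx + cphi * x - sphi * y, cf$cy + sphi * x + cphi * y)
  }
  ederiv <- function(th) {
    x <- -cf$rx * sin(th); y <- cf$ry * cos(th)
    c(cphi * x - sphi * y, sphi * x + cphi * y)
  }
  alpha <- 4 / 3 * tan(dth / 4)
  segs <- vector("list", nseg)
  for (k in seq_len(nseg)) {
    ta <- cf$theta1 + (k - 1) * dth
    tb <- ta + dth
    p0 <- epoint(ta); p3 <- epoint(tb)
    segs[[k]] <- list(p0 = p0, p1 = p0 + alpha * ederiv(ta),
                      p2 = p3 - alpha * ederiv(tb), p3 = p3)
  }
  # snap segment chain ends to the exact endpoints
  segs[[1]]$p0 <- cp
  segs[[nseg]]$p3 <- a[6:7]
  segs
}

#' Planar affine transforms
#'
#' A transform is a 2x3 matrix `[a b tx; c d ty]` mapping
#' `(x, y) -> (a x + b y + tx, c x + d y + ty)`. Constructors cover the
#' compositions the renderer needs: translation, rotation about a point,
#' mirroring, and uniform scaling.
#'
#' @param dx,dy Translation offsets.
#' @return A 2x3 numeric matrix of class `transform2d`.
#' @export
transform_translate <- function(dx, dy) {
  structure(matrix(c(1, 0, 0, 1, dx, dy), 2, 3), class = "transform2d")
}

#' @rdname transform_translate
#' @export
transform_identity <- function() transform_translate(0, 0)

#' @rdname transform_translate
#' @param theta Rotation angle in radians (counter-clockwise in a y-up
#'   frame; on the y-down SVG canvas a positive angle appears clockwise).
#' @param center Point to rotate about / mirror through.
#' @export
transform_rotate <- function(theta, center = c(0, 0)) {
  ct <- cos(theta); st <- sin(theta)
  tx <- center[1] - ct * center[1] + st * center[2]
  ty <- center[2] - st * center[1] - ct * center[2]
  structure(matrix(c(ct, st, -st, ct, tx, ty), 2, 3), class = "transform2d")
}

#' @rdname transform_translate
#' @param axis `"x"` reflects x-coordinates across the vertical line
#'   `x = at`; `"y"` reflects y-coordinates across the horizontal line
#'   `y = at`.
#' @param at Position of the mirror line.
#' @export
transform_mirror <- function(axis = c("x", "y"), at = 0) {
  axis <- match.arg(axis)
  if (axis == "x") {
    structure(matrix(c(-1, 0, 0, 1, 2 * at, 0), 2, 3), class = "transform2d")
  } else {
    structure(matrix(c(1, 0, 0, -1, 0, 2 * at), 2, 3), class = "transform2d")
  }
}

#' @rdname transform_translate
#' @param s Uniform scale factor (nonzero).
#' @export
transform_scale <- function(s, center = c(0, 0)) {
  if (s == 0) stop("scale factor must be nonzero", call. = FALSE)
  structure(matrix(c(s, 0, 0, s, center[1] * (1 - s), center[2] * (1 - s)), 2, 3),
            class = "transform2d")
}

#' @rdname transform_translate
#' @param outer,inner Transforms; the composition applies `inner` first.
#' @export
transform_compose <- function(outer, inner) {
  lin <- outer[, 1:2] %*% inner[, 1:2]
  off <- outer[, 1:2] %*% inner[, 3] + outer[, 3]
  structure(cbind(lin, off), class = "transform2d")
}

transform_point <- function(t, p) {
  as.numeric(t[, 1:2] %*% p + t[, 3])
}

#' Apply a planar transform to path commands
#'
#' All coordinates are mapped through the transform. Elliptical-arc
#' commands keep their `A` form under similarity transforms (translation,
#' rotation, mirroring, uniform scale): the radii are scaled, the
#' x-axis-rotation re-derived, and the sweep flag flipped when the
#' transform reverses orientation. Under a general (shearing) affine map
#' arcs are converted to cubic segments first.
#'
#' @param commands Command list.
#' @param t A `transform2d`.
#' @return A transformed command list.
#' @export
apply_transform <- function(commands, t) {
  lin <- t[, 1:2]
  det <- lin[1, 1] * lin[2, 2] - lin[1, 2] * lin[2, 1]
  if (abs(det) < 1e-12) stop("transform is singular", call. = FALSE)
  col1 <- lin[, 1]; col2 <- lin[, 2]
  is_similarity <- abs(sum(col1^2) - sum(col2^2)) < 1e-9 * (sum(col1^2) + 1) &&
    abs(sum(col1 * col2)) < 1e-9 * (sum(col1^2) + 1)
  scale <- sqrt(sum(col1^2))
  out <- list()
  cp <- c(NA_real_, NA_real_)
  start <- c(NA_real_, NA_real_)
  for (cmd in commands) {
    a <- cmd$args
    new_cp <- switch(cmd$op,
      M = , L = a,
      C = a[5:6],
      Q = a[3:4],
      A = a[6:7],
      Z = start)
    if (cmd$op == "M") start <- a
    if (cmd$op %in% c("M", "L")) {
      out[[length(out) + 1L]] <- list(op = cmd$op, args = transform_point(t, a))
    } else if (cmd$op == "C") {
      out[[length(out) + 1L]] <- list(op = "C", args = c(
        transform_point(t, a[1:2]), transform_point(t, a[3:4]), transform_point(t, a[5:6])))
    } else if (cmd$op == "Q") {
      out[[length(out) + 1L]] <- list(op = "Q", args = c(
        transform_point(t, a[1:2]), transform_point(t, a[3:4])))
    } else if (cmd$op == "Z") {
      out[[length(out) + 1L]] <- list(op = "Z", args = numeric(0))
    } else if (cmd$op == "A") {
      if (is_similarity) {
        phi <- a[3] * pi / 180
        axis <- as.numeric(lin %*% c(cos(phi), sin(phi)))
        phi2 <- atan2(axis[2], axis[1]) * 180 / pi
        sweep <- a[5]
        if (det < 0) sweep <- 1 - sweep
        out[[length(out) + 1L]] <- list(op = "A", args = c(
          a[1] * scale, a[2] * scale, phi2, a[4], sweep, transform_point(t, a[6:7])))
      } else {
        segs <- arc_to_cubics(cp, a)
        for (s in segs) {
          out[[length(out) + 1L]] <- list(op = "C", args = c(
            transform_point(t, s$p1), transform_point(t, s$p2), transform_point(t, s$p3)))
        }
      }
    }
    cp <- new_cp
  }
  out
}
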