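test_that("path data parses with normalization of relative opcodes", {
  expect_equal(parse_path_data("M 0 0 L 10 0"),
               list(list(op = "M", args = c(0, 0)), list(op = "L", args = c(10, 0))))
  expect_equal(parse_path_data("M 0 0 l 10 0"),
               list(list(op = "M", args = c(0, 0)), list(op = "L", args = c(10, 0))))
  # commas accepted, implicit repetition follows SVG semantics
  expect_equal(parse_path_data("M 0,0 L 1,1 2,2"),
               parse_path_data("M 0 0 L 1 1 L 2 2"))
  rel <- parse_path_data("M 1 1 c 1 0 2 0 3 1 q 1 1 2 0 a 2 1 0 0 1 2 0")
  expect_equal(rel[[2]], list(op = "C", args = c(2, 1, 3, 1, 4, 2)))
  expect_equal(rel[[3]], list(op = "Q", args = c(5, 3, 6, 2)))
  expect_equal(rel[[4]], list(op = "A", args = c(2, 1, 0, 0, 1, 8, 2)))
})

test_that("malformed path data is rejected with positions", {
  expect_error(parse_path_data("M 0 0 L 10"), "needs 2 numbers")
  expect_error(parse_path_data("M 0 0 H 5"), "unsupported opcode 'H'")
  expect_error(parse_path_data("L 0 0"), "must start with an M")
  expect_error(parse_path_data("M 0 x"), "not a number")
  expect_error(parse_path_data(""), "non-empty")
})

test_that("serialization round-trips random command lists", {
  set.seed(5)
  rand_num <- function(n) round(stats::runif(n, -100, 100), 3)
  for (i in 1:30) {
    cmds <- list(list(op = "M", args = rand_num(2)))
    for (j in seq_len(sample(1:6, 1))) {
      op <- sample(c("L", "C", "Q", "A", "Z"), 1)
      args <- switch(op,
        L = rand_num(2), C = rand_num(6), Q = rand_num(4),
        A = c(abs(rand_num(2)) + 1, round(stats::runif(1, 0, 90), 1),
              sample(0:1, 1), sample(0:1, 1), rand_num(2)),
        Z = numeric(0))
      cmds[[length(cmds) + 1L]] <- list(op = op, args = args)
    }
    expect_equal(parse_path_data(serialize_path_data(cmds)), cmds)
  }
})

test_that("bounds of polylines and points are the vertex hull", {
  expect_equal(path_bounds("M 0 0 L 10 0 L 5 8 Z"),
               c(xmin = 0, ymin = 0, xmax = 10, ymax = 8))
  expect_equal(path_bounds("M 3 4"), c(xmin = 3, ymin = 4, xmax = 3, ymax = 4))
  expect_error(path_bounds(list()), "empty")
})

test_that("cubic bounds agree with a dense sampling oracle", {
  set.seed(9)
  sample_cubic <- function(p0, p1, p2, p3, n = 10000) {
    t <- seq(0, 1, length.out = n)
    mt <- 1 - t
    x <- mt^3 * p0[1] + 3 * mt^2 * t * p1[1] + 3 * mt * t^2 * p2[1] + t^3 * p3[1]
    y <- mt^3 * p0[2] + 3 * mt^2 * t * p1[2] + 3 * mt * t^2 * p2[2] + t^3 * p3[2]
    c(xmin = min(x), ymin = min(y), xmax = max(x), ymax = max(y))
  }
  for (i in 1:25) {
    pts <- matrix(stats::runif(8, -50, 50), 2)
    cmds <- list(list(op = "M", args = pts[, 1]),
                 list(op = "C", args = c(pts[, 2], pts[, 3], pts[, 4])))
    got <- path_bounds(cmds)
    ref <- sample_cubic(pts[, 1], pts[, 2], pts[, 3], pts[, 4])
    span <- max(ref[["xmax"]] - ref[["xmin"]], ref[["ymax"]] - ref[["ymin"]], 1)
    expect_lt(max(abs(got - ref)), 1e-6 * span)
  }
})

test_that("arc bounds match analytic ellipse extents", {
  # half circle above the baseline (y-down coordinates)
  b <- path_bounds("M 0 0 A 6 6 0 0 1 12 0")
  expect_equal(b, c(xmin = 0, ymin = -6, xmax = 12, ymax = 0), tolerance = 1e-6)
  # half ellipse with ry != rx
  b2 <- path_bounds("M 0 0 A 6 3 0 0 1 12 0")
  expect_equal(b2[["ymin"]], -3, tolerance = 1e-6)
  # full circle built from two half arcs spans the whole disc
  b3 <- path_bounds("M 0 -7 A 7 7 0 0 1 14 -7 A 7 7 0 0 1 0 -7 Z")
  expect_equal(b3, c(xmin = 0, ymin = -14, xmax = 14, ymax = 0), tolerance = 1e-6)
})

test_that("transforms move points as specified", {
  tr <- transform_translate(100, 50)
  expect_equal(apply_transform(list(list(op = "M", args = c(0, 0))), tr)[[1]]$args,
               c(100, 50))
  rot <- transform_rotate(pi, c(15, 0))
  expect_equal(apply_transform(list(list(op = "M", args = c(0, 0))), rot)[[1]]$args,
               c(30, 0), tolerance = 1e-12)
  expect_error(apply_transform(list(list(op = "M", args = c(0, 0))),
                               structure(matrix(0, 2, 3), class = "transform2d")),
               "singular")
})

test_that("mirror and half-turn rotations are involutions on curves and arcs", {
  d <- "M 0 0 L 10 0 C 12 -4 14 -4 16 0 Q 18 4 20 0 A 3 2 30 0 1 26 0 Z"
  cmds <- parse_path_data(d)
  for (tf in list(transform_mirror("x", at = 7), transform_mirror("y", at = -2),
                  transform_rotate(pi, c(13, 1)))) {
    twice <- apply_transform(apply_transform(cmds, tf), tf)
    dev <- max(mapply(function(a, b) {
      if (length(a$args) == 0) 0 else max(abs(a$args - b$args) %% 360)
    }, cmds, twice))
    expect_lt(dev, 1e-9)
  }
})

test_that("bounds are covariant under pure translation", {
  set.seed(21)
  for (i in 1:20) {
    cmds <- parse_path_data(sprintf("M %g %g L %g %g C %g %g %g %g %g %g",
                                    stats::runif(1, -9, 9), stats::runif(1, -9, 9),
                                    stats::runif(1, -9, 9), stats::runif(1, -9, 9),
                                    stats::runif(1, -9, 9), stats::runif(1, -9, 9),
                                    stats::runif(1, -9, 9), stats::runif(1, -9, 9),
                                    stats::runif(1, -9, 9), stats::runif(1, -9, 9)))
    dx <- stats::runif(1, -50, 50)
    dy <- stats::runif(1, -50, 50)
    b0 <- path_bounds(cmds)
    b1 <- path_bounds(apply_transform(cmds, transform_translate(dx, dy)))
    expect_equal(b1, b0 + c(dx, dy, dx, dy), tolerance = 1e-9)
  }
})

test_that("templates substitute expressions and reject malformed braces", {
  expect_equal(evaluate_template("M {0} {0} L {width} {0}", c(width = 30)),
               "M 0 0 L 30 0")
  expect_equal(evaluate_template("M 0 {-height/2}", c(height = 15)), "M 0 -7.5")
  expect_error(evaluate_template("M {width 0", c(width = 1)), "malformed braces")
  expect_error(evaluate_template("M {width} 0"), "'width'")
  expect_setequal(template_parameters("M {width} {height - pad} L 3 {width}"),
                  c("width", "height", "pad"))
})
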