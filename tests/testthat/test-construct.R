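lib <- make_fixture_library()

cds_of_width <- function(w) part("CDS", user_parameters = c(width = w))

test_that("anchors chain: next anchor = previous baseline end + spacing", {
  spec <- construct_spec(parts(cds_of_width(30), cds_of_width(20), cds_of_width(40)),
                         part_spacing = 5)
  lay <- layout_parts(spec, lib)
  expect_equal(lay$anchor_x, c(0, 35, 60))
  expect_equal(lay$baseline_end_x[3], 100)
  expect_true(all(lay$anchor_y == 0))
})

test_that("an empty parts list lays out and renders to nothing", {
  spec <- construct_spec()
  expect_identical(nrow(layout_parts(spec, lib)), 0L)
  cv <- svg_canvas()
  b <- render_construct(spec, lib, cv)
  expect_equal(unname(b), c(0, 0, 0, 0))
  expect_silent(xml2::read_xml(canvas_finalize(cv)))
  expect_identical(canvas_path_count(cv), 0L)
})

test_that("reversing parts does not move any anchor", {
  fwd <- construct_spec(parts(part("Promoter"), part("CDS"), part("Terminator")),
                        part_spacing = 3)
  mix <- construct_spec(parts(part("Promoter"), part("CDS", orientation = "reverse"),
                              part("Terminator")), part_spacing = 3)
  expect_equal(layout_parts(mix, lib)$anchor_x, layout_parts(fwd, lib)$anchor_x)
  expect_equal(layout_parts(mix, lib)$baseline_end_x,
               layout_parts(fwd, lib)$baseline_end_x)
})

test_that("random constructs satisfy the chaining invariant exactly", {
  set.seed(31)
  types <- names(lib)
  for (trial in 1:100) {
    n <- sample(1:10, 1)
    # dyadic spacings/starts and integer glyph widths make the chaining
    # arithmetic exact in binary floating point, so equality can be strict
    spacing <- sample(0:48, 1) * 0.25
    pl <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      part(sample(types, 1), orientation = sample(c("forward", "reverse"), 1))
    }))
    spec <- construct_spec(pl, part_spacing = spacing,
                           start = c(sample(-200:200, 1) * 0.25, 0))
    lay <- layout_parts(spec, lib)
    if (n > 1) {
      expect_identical(lay$anchor_x[-1] - lay$baseline_end_x[-n], rep(spacing, n - 1))
    }
    expect_identical(unique(lay$anchor_y), 0)
    # total width identity for a single row
    spans <- lay$baseline_end_x - lay$anchor_x
    expect_equal(lay$baseline_end_x[n] - lay$anchor_x[1],
                 sum(spans) + (n - 1) * spacing)
  }
})

test_that("greedy wrapping fills rows left to right", {
  spec <- construct_spec(parts(cds_of_width(30), cds_of_width(30), cds_of_width(30)),
                         part_spacing = 0, max_line_width = 70)
  rows <- wrap_lines(spec, lib)
  expect_identical(lengths(rows), c(2L, 1L))
  # an oversized part still gets a row
  spec2 <- construct_spec(parts(cds_of_width(200)), max_line_width = 100)
  expect_identical(wrap_lines(spec2, lib), list(1L))
})

test_that("wrapping conserves parts and respects the width limit", {
  set.seed(17)
  for (trial in 1:20) {
    n <- sample(5:100, 1)
    widths <- round(stats::runif(n, 11, 60), 2)
    spacing <- round(stats::runif(1, 0, 6), 2)
    maxw <- round(stats::runif(1, 60, 160), 2)
    pl <- dplyr::bind_rows(lapply(widths, cds_of_width))
    spec <- construct_spec(pl, part_spacing = spacing, max_line_width = maxw)
    rows <- wrap_lines(spec, lib)
    expect_identical(unlist(rows), seq_len(n)) # order and multiset conserved
    # independent re-simulation of the greedy rule
    expected <- list()
    cur <- integer(0)
    w <- 0
    for (i in seq_len(n)) {
      cost <- if (length(cur)) spacing + widths[i] else widths[i]
      if (length(cur) && w + cost > maxw) {
        expected[[length(expected) + 1L]] <- cur
        cur <- integer(0); w <- 0; cost <- widths[i]
      }
      cur <- c(cur, i); w <- w + cost
    }
    expected[[length(expected) + 1L]] <- cur
    expect_identical(rows, expected)
    for (row in rows) {
      if (length(row) > 1L) {
        expect_lte(sum(widths[row]) + (length(row) - 1) * spacing, maxw)
      }
    }
  }
})

arc_apex_y <- function(svg, id) {
  min(path_bounds(parse_path_data(svg_path_d(svg, id)))[["ymin"]])
}

test_that("a single arc clears the whole span at the base clearance", {
  spec <- construct_spec(parts(part("Promoter"), part("RBS"), part("CDS")),
                         interactions = interaction(0, 2, "inhibition", "red"),
                         part_spacing = 5)
  cv <- svg_canvas()
  render_construct(spec, lib, cv)
  svg <- canvas_finalize(cv)
  lay <- layout_parts(spec, lib)
  tallest <- max(-lay$ymin) # promoter: height + arrowhead_height = 18
  expect_equal(arc_apex_y(svg, "interaction.0.arc"), -1.2 * tallest)
  expect_true("interaction.0.bar" %in% svg_path_ids(svg))
})

test_that("overlapping arcs stack deterministically one level apart", {
  spec <- construct_spec(parts(part("CDS"), part("CDS"), part("CDS")),
                         interactions = dplyr::bind_rows(
                           interaction(0, 2, "inhibition", "red"),
                           interaction(1, 2, "control", "blue")),
                         part_spacing = 5, level_step = 6)
  render_one <- function() {
    cv <- svg_canvas()
    render_construct(spec, lib, cv)
    canvas_finalize(cv)
  }
  svg <- render_one()
  y0 <- arc_apex_y(svg, "interaction.0.arc")
  y1 <- arc_apex_y(svg, "interaction.1.arc")
  expect_equal(y1, y0 - 6) # second arc one level higher (y-down canvas)
  expect_true(all(c("interaction.0.bar", "interaction.1.diamond") %in% svg_path_ids(svg)))
  expect_identical(svg, render_one()) # identical spec -> identical arcs
})

test_that("disjoint arcs share the lowest level", {
  spec <- construct_spec(parts(part("CDS"), part("CDS"), part("CDS"), part("CDS")),
                         interactions = dplyr::bind_rows(
                           interaction(0, 1, "inhibition", "red"),
                           interaction(2, 3, "inhibition", "red")),
                         part_spacing = 5)
  cv <- svg_canvas()
  render_construct(spec, lib, cv)
  svg <- canvas_finalize(cv)
  expect_equal(arc_apex_y(svg, "interaction.0.arc"),
               arc_apex_y(svg, "interaction.1.arc"))
})

test_that("interaction indices are validated against the part count", {
  pl <- parts(part("CDS"), part("CDS"))
  expect_error(construct_spec(pl, interaction(0, 2, "inhibition")), "out of range")
  expect_error(interaction(1, 1, "control"), "distinct")
})

test_that("a shorthand-style design renders four glyphs and one barred arc", {
  spec <- construct_spec(parse_design_string("p r c t"),
                         interactions = parse_interaction_string("0//2//in//red"),
                         part_spacing = 5)
  cv <- svg_canvas()
  render_construct(spec, lib, cv)
  svg <- canvas_finalize(cv)
  ids <- svg_path_ids(svg)
  glyph_ids <- grep("^(Promoter|RBS|CDS|Terminator)\\.", ids, value = TRUE)
  instance <- unique(sub(".*\\.", "", glyph_ids))
  expect_identical(length(instance), 4L) # four glyph instances
  expect_identical(sum(grepl("^interaction\\.[0-9]+\\.arc$", ids)), 1L)
  expect_true("interaction.0.bar" %in% ids)
  expect_match(svg_path_style(svg, "interaction.0.arc"), "stroke:#ff0000")
})

test_that("wrapped rows are laid out exactly line_spacing apart", {
  spec <- construct_spec(parts(cds_of_width(40), cds_of_width(40), cds_of_width(40)),
                         part_spacing = 0, max_line_width = 80, line_spacing = 50,
                         start = c(0, 10))
  cv <- svg_canvas()
  render_construct(spec, lib, cv)
  svg <- canvas_finalize(cv)
  row0 <- parse_path_data(svg_path_d(svg, "backbone.0"))
  row1 <- parse_path_data(svg_path_d(svg, "backbone.1"))
  expect_equal(row0[[1]]$args[2], 10)
  expect_equal(row1[[1]]$args[2], 60)
  expect_identical(sum(grepl("^CDS\\.body\\.", svg_path_ids(svg))), 2L + 1L)
})

test_that("labels are drawn beneath their parts", {
  spec <- construct_spec(parts(part("CDS", label = "gfp")))
  cv <- svg_canvas()
  render_construct(spec, lib, cv)
  svg <- canvas_finalize(cv)
  doc <- xml2::read_xml(svg)
  txt <- xml2::xml_find_first(doc, ".//*[local-name()='text']")
  expect_identical(xml2::xml_text(txt), "gfp")
  expect_gt(as.numeric(xml2::xml_attr(txt, "y")), 0)
})
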