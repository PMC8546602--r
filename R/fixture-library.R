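#' Bundled SBOL Visual glyph library
#'
#' Builds a representative subset of the SBOL Visual glyph set as parametric
#' definitions: the five sequence features used by the design shorthand
#' (Promoter, RBS, CDS, Terminator, RecombinationSite) plus two molecular
#' species (Protein, SmallMolecule). Conventions follow the standard's
#' guidance for customizable glyphs:
#'
#' * the CDS is a pentagon over `width`, `height` and `arrowhead_width`, so
#'   stretching `width` lengthens the arrow body while the head keeps its
#'   shape;
#' * stem-and-head glyphs (Promoter, Terminator) share parameter names
#'   (`width`, `height`, ...), as do the round molecular-species glyphs;
#' * defaults are chosen so the uncustomized shapes are clearly
#'   distinguishable when composed on one baseline.
#'
#' Glyph files use SVG screen coordinates (y grows downward), the baseline
#' at `y = 0`, and the anchor at `x = 0`; the baseline spans the bounding
#' box, so a glyph's baseline span is its composition width.
#'
#' @param directory Optional: also write one pSVG file per glyph here
#'   (created if needed).
#' @return A `glyph_library` with the 7 definitions.
#' @examples
#' lib <- make_fixture_library()
#' names(lib)
#' @export
make_fixture_library <- function(directory = NULL) {
  glyphs <- list(
    fixture_promoter(), fixture_rbs(), fixture_cds(), fixture_terminator(),
    fixture_recombination_site(), fixture_protein(), fixture_small_molecule())
  lib <- as_glyph_library(glyphs)
  if (!is.null(directory)) {
    if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
    for (g in lib) {
      write_glyph(g, file.path(directory, paste0(tolower(g$glyph_type), ".psvg")))
    }
  }
  lib
}

fixture_cds <- function() {
  defaults <- c(width = 30, height = 15, arrowhead_width = 10)
  body <- parametric_path(
    "body",
    parametric_d = paste(
      "M 0 {-height/2}",
      "L {width - arrowhead_width} {-height/2}",
      "L {width} 0",
      "L {width - arrowhead_width} {height/2}",
      "L 0 {height/2} Z"),
    style = list(fill = "green", stroke = "black", stroke_width = 1),
    defaults = defaults)
  glyph_definition(
    "CDS", list(body), defaults,
    baseline_d = "M 0 0 L {width} 0",
    bounding_box_d = "M 0 {-height/2} L {width} {-height/2} L {width} {height/2} L 0 {height/2} Z")
}

fixture_promoter <- function() {
  defaults <- c(width = 12, height = 15, arrowhead_width = 4, arrowhead_height = 3)
  stem <- parametric_path(
    "stem", parametric_d = "M 0 0 L 0 {-height}",
    style = list(fill = "none", stroke = "black", stroke_width = 1.5),
    defaults = defaults)
  head <- parametric_path(
    "head",
    parametric_d = paste(
      "M 0 {-height} L {width} {-height}",
      "M {width - arrowhead_width} {-height - arrowhead_height}",
      "L {width} {-height}",
      "L {width - arrowhead_width} {-height + arrowhead_height}"),
    style = list(fill = "none", stroke = "black", stroke_width = 1.5),
    defaults = defaults)
  glyph_definition(
    "Promoter", list(stem, head), defaults,
    baseline_d = "M 0 0 L {width} 0",
    bounding_box_d = paste(
      "M 0 {-height - arrowhead_height} L {width} {-height - arrowhead_height}",
      "L {width} 0 L 0 0 Z"))
}

fixture_terminator <- function() {
  defaults <- c(width = 12, height = 12)
  stem <- parametric_path(
    "stem", parametric_d = "M {width/2} 0 L {width/2} {-height}",
    style = list(fill = "none", stroke = "black", stroke_width = 1.5),
    defaults = defaults)
  head <- parametric_path(
    "head", parametric_d = "M 0 {-height} L {width} {-height}",
    style = list(fill = "none", stroke = "black", stroke_width = 1.5),
    defaults = defaults)
  glyph_definition(
    "Terminator", list(stem, head), defaults,
    baseline_d = "M 0 0 L {width} 0",
    bounding_box_d = "M 0 {-height} L {width} {-height} L {width} 0 L 0 0 Z")
}

fixture_rbs <- function() {
  defaults <- c(width = 12, height = 6)
  disc <- parametric_path(
    "disc", parametric_d = "M 0 0 A {width/2} {height} 0 0 1 {width} 0 Z",
    style = list(fill = "cornflowerblue", stroke = "black", stroke_width = 1),
    defaults = defaults)
  glyph_definition(
    "RBS", list(disc), defaults,
    baseline_d = "M 0 0 L {width} 0",
    bounding_box_d = "M 0 {-height} L {width} {-height} L {width} 0 L 0 0 Z")
}

fixture_recombination_site <- function() {
  defaults <- c(width = 10, height = 10)
  tri <- parametric_path(
    "triangle", parametric_d = "M 0 0 L {width} 0 L {width/2} {-height} Z",
    style = list(fill = "orange", stroke = "black", stroke_width = 1),
    defaults = defaults)
  glyph_definition(
    "RecombinationSite", list(tri), defaults,
    baseline_d = "M 0 0 L {width} 0",
    bounding_box_d = "M 0 {-height} L {width} {-height} L {width} 0 L 0 0 Z")
}

# round molecular-species glyph sitting just above the baseline,
# drawn as two half-ellipse arcs
species_body_d <- paste(
  "M 0 {-height/2}",
  "A {width/2} {height/2} 0 0 1 {width} {-height/2}",
  "A {width/2} {height/2} 0 0 1 0 {-height/2} Z")

fixture_protein <- function() {
  defaults <- c(width = 14, height = 14)
  body <- parametric_path(
    "body", parametric_d = species_body_d,
    style = list(fill = "lightgray", stroke = "black", stroke_width = 1),
    defaults = defaults)
  glyph_definition(
    "Protein", list(body), defaults,
    baseline_d = "M 0 0 L {width} 0",
    bounding_box_d = "M 0 {-height} L {width} {-height} L {width} 0 L 0 0 Z")
}

fixture_small_molecule <- function() {
  defaults <- c(width = 8, height = 8)
  body <- parametric_path(
    "body", parametric_d = species_body_d,
    style = list(fill = "white", stroke = "black", stroke_width = 1),
    defaults = defaults)
  glyph_definition(
    "SmallMolecule", list(body), defaults,
    baseline_d = "M 0 0 L {width} 0",
    bounding_box_d = "M 0 {-height} L {width} {-height} L {width} 0 L 0 0 Z")
}
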