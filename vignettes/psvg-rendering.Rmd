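---
title: "Parametric glyphs and diagram composition with sbolvis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric glyphs and diagram composition with sbolvis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbolvis)
```

## The problem

SBOL Visual (SBOLv) standardizes the symbols used to draw engineered
genetic designs: a bent arrow for a promoter, a half-disc for a ribosome
binding site, a thick arrow for a coding sequence, and so on. The standard
also permits controlled customization — a long CDS may be drawn with a
stretched body but an unchanged arrowhead, and fills may encode function —
and the glyph set keeps growing. Tools that hard-code one drawing routine
per glyph accumulate maintenance debt with every standard revision.

sbolvis instead treats each glyph as *data*: a parametric SVG (pSVG) file.
A pSVG file is an ordinary SVG file in which any path coordinate may also
be given as an arithmetic expression over named parameters, with defaults
stored in the file itself. One generic rendering code path can then draw
every glyph, current or future, and customization becomes a matter of
passing parameter values rather than editing code.

## The pSVG dialect

A glyph file is well-formed SVG with three supplemental attributes in a
`parametric` XML namespace:

* `parametric:defaults` on the root `svg` element — semicolon-separated
  `name=value` pairs giving every parameter's default;
* `parametric:type` on the root — the SBOLv term the file defines;
* `parametric:d` on any `path` element — the path-data template, identical
  to `d` except that coordinates may be `{expression}` forms such as
  `{width - arrowhead_width}` or `{-height/2}`.

Every path keeps a plain `d` attribute holding the shape evaluated at the
defaults, so stripping the `parametric:*` attributes leaves a valid static
SVG that any viewer renders — backward compatibility is a structural
property of the format, and `validate_glyph()` enforces the corresponding
invariant: template evaluated at defaults must reproduce the static path
to within 1e-9 per coordinate.

Two specially named paths carry the composition contract rather than
visible ink. `id="baseline"` is a horizontal segment — the DNA strand the
glyph sits on; its start is the glyph's anchor and its end is where the
next glyph begins. `id="bounding-box"` declares the space the glyph
occupies. Both may themselves be parametric so they track geometry
overrides. The baseline must be horizontal and span the bounding box
horizontally, the box must have positive width, and the default geometry
must lie inside the box (tolerance 1e-6); violations are load errors.

Files use SVG screen coordinates: y grows downward, so glyphs drawn
"above" the strand have negative y. All bounds are closed intervals.

## Expressions

The expression language is deliberately small: decimal literals (optional
fraction and exponent), parameter names, `+ - * /` with standard
precedence and left associativity, unary minus binding tighter than `*`
and `/`, parentheses, and the function table `sin`, `cos`, `tan`, `sqrt`,
`abs` (unary, radians) plus binary `min` and `max`. Whitespace is
insignificant. Division by zero is an evaluation error, never an infinity,
and an unbound parameter is reported by name. Unknown parameters are
detected at evaluation time, not parse time, so a library can be parsed
before any user values exist.

```{r}
evaluate_expression("width - arrowhead_width", c(width = 30, arrowhead_width = 10))
expression_parameters("min(width, height) / 2")
```

## The bundled glyph library

`make_fixture_library()` builds seven glyphs covering the design-shorthand
vocabulary — Promoter, RBS, CDS, Terminator, RecombinationSite — plus two
molecular species, Protein and SmallMolecule. Conventions mirror the
standard's practice: glyph subsets share parameter names (the
stem-and-head pair Promoter/Terminator both use `width` and `height`; the
round species glyphs share `width`/`height` too), and defaults were chosen
once so the uncustomized shapes are clearly distinguishable side by side.

The CDS pentagon is the canonical example of controlled customization:

```{r}
lib <- make_fixture_library()
lib$CDS$paths[[1]]$parametric_d
lib$CDS$defaults
```

Because only the body vertices depend on `width - arrowhead_width`,
stretching `width` lengthens the body while the arrowhead keeps its exact
shape.

## Rendering and composition

`draw_glyph()` evaluates the templates at the resolved parameters
(defaults overlaid by `user_parameters`; unknown names are rejected with
the valid list), positions the geometry so the baseline start sits at the
anchor, paints each path with its default style overlaid by `user_style`
(a list keyed by path name), and returns the contract: the transformed
bounding box and the baseline end point.

```{r}
cv <- svg_canvas()
res <- draw_glyph(lib, "CDS", anchor = c(100, 50),
                  user_parameters = c(width = 60), canvas = cv)
res$baseline_end
```

Reverse orientation rotates the evaluated geometry 180 degrees about the
midpoint of its own baseline before anchoring. A rotation (rather than a
vertical mirror) was chosen because it matches the standard's convention
for reverse-strand parts: the glyph flips below the baseline *and* points
the other way, while the baseline extent — and therefore all layout — is
unchanged. Rotation is also an exact involution, which the tests exploit.

`render_construct()` chains parts along a row (each anchor is the previous
baseline end plus `part_spacing`), draws a continuous backbone line under
each row, and routes interaction arcs above the parts. Arc clearance is
`base_clearance + level * level_step`; the default base clearance is 1.2
times the tallest glyph in the arc's span (collision-free for the bundled
defaults) and `level_step` is 6 units, both configurable in
`construct_spec()`. An arc's stacking level counts the earlier arcs whose
part-index span overlaps its own, processed in input order, so identical
specifications always yield identical arc geometry. Terminal decorations
follow the field's iconography: a perpendicular bar for inhibition, an
open diamond for control, an open arrowhead for stimulation (the last is
reachable from the API but not from the shorthand, whose vocabulary only
has `in` and `co`).

When `max_line_width` is set, rows fill greedily left to right: a part
opens a new row when adding it would exceed the limit, unless it would be
the row's first part — an oversized part gets a row to itself rather than
being dropped or scaled. An interaction whose endpoints land on different
rows is drawn in the source part's row and truncated at the row edge
without a terminal; with no stated convention for cross-row arcs in the
standard, truncation was preferred over multi-row routing because it keeps
every row's vertical extent independent of the others.

## The shorthand and GenBank front ends

`parse_design_string()` implements the command-line notation: tokens are
whitespace-separated, `<` reverses a part, the codes `p r c t x` map to the
five sequence features, and `.color` attaches a fill to the glyph's primary
path. The delimiters (whitespace between tokens, `.` before a color) are
this package's micro-syntax choice; colors accept names, hex triplets, and
the `l_` prefix meaning "blend each RGB channel 50% toward white" — a
factor chosen to be visually distinct yet invertible enough to test
(`l_blue` is exactly RGB 128,128,255). Interactions are single strings of
four `//`-separated fields, `start//end//type//color`, with 0-based part
indices as in the notation itself.

`genbank_to_parts()` converts an annotated record: CDS features (the
retained set is configurable) become CDS glyphs ordered by start
coordinate, reverse-strand features are reversed, and `width_hint =
max(min_width, length * scale)` with the GenBank 1-based inclusive length
`end - start + 1`. Above the floor, width ratios equal length ratios
exactly. Intergenic gaps are *not* drawn to scale — parts pack with uniform
spacing, since the claim is correct relative sizes of coding regions, not a
genome browser. Color rules are ordered case-insensitive substring patterns
matched against `/product` and `/function`, first match wins, with a gray
default. `genbank_fixture()` generates deterministic synthetic records
(lengths 150–1500 nt, gaps 50–400 nt, random strands and products from a
fixed vocabulary) for tests and demonstrations; it emulates the feature
table of a real record but not its sequence, multi-line qualifiers, or
compound locations beyond overall spans — conclusions about those require
real files.

## Numerical choices

* Path data supports absolute `M L C Q A Z` (lowercase relative forms are
  normalized at parse time); `H V S T` are excluded and the bundled glyphs
  avoid them.
* Serialized numbers carry up to 9 significant digits with trailing zeros
  trimmed, which keeps the 1e-9 default-identity tolerance meaningful.
* Bounds are exact for lines and Bezier segments (derivative extrema);
  elliptical arcs are converted to cubic segments of at most pi/8 radians,
  whose approximation error (about 1e-7 of the radius) sits well under the
  1e-6 bounds tolerance.
* Under similarity transforms (all this package produces: translation,
  rotation, mirroring, uniform scale) arc commands are transformed
  exactly — radii scaled, axis rotation re-derived, sweep flipped on
  reflection — so reverse-of-reverse restores coordinates to better than
  1e-9; a general shearing affine would fall back to cubic conversion.
* Degenerate inputs have defined behavior: a lone `M` yields point bounds,
  an empty construct renders an empty valid document with a default view
  box, and an empty parts table lays out to zero rows.

## Scope and limitations

The bundled library is a representative subset, not the full SBOLv
catalogue; the format and renderer carry the rest unchanged (a new glyph
is a new file, not new code). SVG features beyond path elements (text on
paths, gradients, transform attributes in input files) are out of scope,
as are stroke-aware "ink" bounds, circular plasmid layout, and automatic
arc-crossing minimization. Test sizes (1000 random expressions, 100 random
constructs, 50 random glyph round trips, 12-CDS records) were picked so
the whole suite exercises every property in seconds; all are trivially
enlargeable.
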