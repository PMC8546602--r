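Package: sbolvis
Title: Parametric SVG Glyphs and Diagram Rendering for SBOL Visual
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reads, validates, writes and renders parametric SVG (pSVG)
    glyph definitions for SBOL Visual genetic design diagrams. A pSVG file
    is an ordinary SVG file whose path coordinates may additionally be
    given as arithmetic expressions over named parameters with stored
    defaults, so one rendering code path can draw every glyph in the
    standard and allow controlled customization (for example stretching a
    coding-sequence arrow's body but not its head). Includes an expression
    engine, SVG path-data geometry with tight bounds and planar
    transforms, a glyph renderer returning the baseline composition
    contract, whole-construct layout with regulatory interaction arcs and
    line wrapping, a command-line design shorthand, and a GenBank
    feature-to-diagram converter with proportional part sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    grDevices,
    stats,
    tibble,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
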