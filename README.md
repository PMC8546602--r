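# sbolvis

Render SBOL Visual genetic design diagrams in R from machine-readable,
parametric glyph definitions.

## Why

Synthetic biologists communicate designs with SBOL Visual (SBOLv)
diagrams: a bent arrow for a promoter, a half-disc for an RBS, a thick
arrow for a CDS, an arc ending in a bar for repression. The standard
allows controlled customization — a long coding sequence is drawn by
stretching the arrow's *body*, never its head — and its glyph set keeps
growing, so tools that hard-code one drawing function per glyph are
expensive to keep current.

sbolvis makes the glyph a data file instead. A **parametric SVG (pSVG)**
glyph is ordinary SVG whose path coordinates may be arithmetic expressions
over named parameters, e.g.

```
parametric:d = "M 0 {-height/2} L {width - arrowhead_width} {-height/2}
                L {width} 0 L {width - arrowhead_width} {height/2}
                L 0 {height/2} Z"
parametric:defaults = "width=30;height=15;arrowhead_width=10"
```

with the defaults stored in the file. Every path also keeps its ordinary
`d` attribute baked at the defaults, so a pSVG file is valid plain SVG for
any other tool. Each glyph additionally declares a **baseline** (the DNA
strand segment; its start is the anchor, its end locates the next glyph)
and a **bounding box**, which is all a renderer needs to compose whole
constructs from any glyph, current or future, with one code path.

The package provides:

* an expression engine (`+ - * /`, parentheses, unary minus, `sin cos tan
  sqrt abs min max`, radians) and SVG path geometry (parser, tight bounds
  including Bezier/arc extrema, planar transforms);
* reading, validation, writing and programmatic generation of pSVG glyph
  libraries (`read_glyph()`, `write_glyph()`, `load_library()`,
  `make_fixture_library()` — seven bundled SBOLv glyphs, also installed
  under `inst/extdata/glyphs/`);
* a glyph renderer with geometry and style overrides returning the
  composition contract (`draw_glyph()` → bounds + baseline end);
* whole-construct layout: baseline chaining, regulatory interaction arcs
  with kind-specific terminals, greedy line wrapping
  (`construct_spec()`, `layout_parts()`, `render_construct()`);
* the design shorthand (`parse_design_string("p r c.green t")`,
  `parse_interaction_string("0//2//in//red")`) and a GenBank converter
  with length-proportional part widths and function-based coloring
  (`read_genbank()`, `genbank_to_parts()`, `render_genbank()`);
* a CLI (`exec/sbolv`) wrapping the above: `sbolv draw`, `sbolv genbank`,
  `sbolv genbank-fixture`, `sbolv glyphs init`.

## Worked example

```r
library(sbolvis)
lib <- make_fixture_library()

# one glyph: a CDS stretched to width 60 at anchor (100, 50)
cv <- svg_canvas()
draw_glyph(lib, "CDS", anchor = c(100, 50),
           user_parameters = c(width = 60), canvas = cv)
#> <render result: baseline (100,50) -> (160,50); bounds [100,160] x [42.5,57.5]>
```

The baseline end `(160, 50)` is where the next part would start; the
bounds are symmetric about the baseline because a CDS straddles the
strand. The arrowhead is still 10 units — only the body stretched.

```r
# a whole construct from shorthand, with a repression arc
design <- parse_design_string("p r c.green t")
spec   <- construct_spec(design,
                         interactions = parse_interaction_string("0//2//in//red"),
                         part_spacing = 5)
layout_parts(spec, lib)
#> # A tibble: 4 × 10
#>   part_index glyph_type orientation anchor_x anchor_y baseline_end_x  xmin  ymin
#>        <int> <chr>      <chr>          <dbl>    <dbl>          <dbl> <dbl> <dbl>
#> 1          1 Promoter   forward            0        0             12     0 -18
#> 2          2 RBS        forward           17        0             29    17  -6
#> 3          3 CDS        forward           34        0             64    34  -7.5
#> 4          4 Terminator forward           69        0             81    69 -12
```

Each anchor is the previous baseline end plus the 5-unit spacing
(12 + 5 = 17, 29 + 5 = 34, ...). Rendering draws the backbone, the four
glyphs and the arc (stroke red, bar terminal above the CDS) and returns
the union bounds; `canvas_finalize()` yields the SVG document:

```r
cv <- svg_canvas()
render_construct(spec, lib, cv)
#>  xmin  ymin  xmax  ymax
#>   0.0 -21.6  81.0   7.5
canvas_finalize(cv, file = "construct.svg")
```

The arc apex at y = −21.6 is 1.2 × the tallest glyph in its span (the
18-unit promoter). From the shell, the same figure is:

```sh
sbolv draw --string "p r c.green t" --interaction "0//2//in//red" \
      --output construct.svg
```

And a wrapped genome-style view of an annotated record:

```r
rec <- read_genbank("record.gb")   # or genbank_fixture(12, seed = 1)
cv <- svg_canvas()
render_genbank(rec, feature_mapping(rules = c(polymerase = "purple")),
               max_line_width = 120, canvas = cv)
canvas_finalize(cv, file = "genome.svg")
```

CDS widths are proportional to feature lengths (floored at a minimum
width), complement-strand features point left, and rows wrap greedily at
120 units preserving genomic order.

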