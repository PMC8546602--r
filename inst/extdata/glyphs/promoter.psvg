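<svg xmlns="http://www.w3.org/2000/svg" xmlns:parametric="https://parametric-svg.github.io/v0.2" parametric:type="Promoter" parametric:defaults="width=12;height=15;arrowhead_width=4;arrowhead_height=3" viewBox="0 -18 12 18">
  <path id="stem" d="M 0 0 L 0 -15" parametric:d="M 0 0 L 0 {-height}" style="fill:none;stroke:black;stroke-width:1.5"/>
  <path id="head" d="M 0 -15 L 12 -15 M 8 -18 L 12 -15 L 8 -12" parametric:d="M 0 {-height} L {width} {-height} M {width - arrowhead_width} {-height - arrowhead_height} L {width} {-height} L {width - arrowhead_width} {-height + arrowhead_height}" style="fill:none;stroke:black;stroke-width:1.5"/>
  <path id="baseline" d="M 0 0 L 12 0" parametric:d="M 0 0 L {width} 0" style="fill:none;stroke:none"/>
  <path id="bounding-box" d="M 0 -18 L 12 -18 L 12 0 L 0 0 Z" parametric:d="M 0 {-height - arrowhead_height} L {width} {-height - arrowhead_height} L {width} 0 L 0 0 Z" style="fill:none;stroke:none"/>
</svg>
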