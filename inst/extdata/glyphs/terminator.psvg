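<svg xmlns="http://www.w3.org/2000/svg" xmlns:parametric="https://parametric-svg.github.io/v0.2" parametric:type="Terminator" parametric:defaults="width=12;height=12" viewBox="0 -12 12 12">
  <path id="stem" d="M 6 0 L 6 -12" parametric:d="M {width/2} 0 L {width/2} {-height}" style="fill:none;stroke:black;stroke-width:1.5"/>
  <path id="head" d="M 0 -12 L 12 -12" parametric:d="M 0 {-height} L {width} {-height}" style="fill:none;stroke:black;stroke-width:1.5"/>
  <path id="baseline" d="M 0 0 L 12 0" parametric:d="M 0 0 L {width} 0" style="fill:none;stroke:none"/>
  <path id="bounding-box" d="M 0 -12 L 12 -12 L 12 0 L 0 0 Z" parametric:d="M 0 {-height} L {width} {-height} L {width} 0 L 0 0 Z" style="fill:none;stroke:none"/>
</svg>
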