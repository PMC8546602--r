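<svg xmlns="http://www.w3.org/2000/svg" xmlns:parametric="https://parametric-svg.github.io/v0.2" parametric:type="RBS" parametric:defaults="width=12;height=6" viewBox="0 -6 12 6">
  <path id="disc" d="M 0 0 A 6 6 0 0 1 12 0 Z" parametric:d="M 0 0 A {width/2} {height} 0 0 1 {width} 0 Z" style="fill:cornflowerblue;stroke:black;stroke-width:1"/>
  <path id="baseline" d="M 0 0 L 12 0" parametric:d="M 0 0 L {width} 0" style="fill:none;stroke:none"/>
  <path id="bounding-box" d="M 0 -6 L 12 -6 L 12 0 L 0 0 Z" parametric:d="M 0 {-height} L {width} {-height} L {width} 0 L 0 0 Z" style="fill:none;stroke:none"/>
</svg>
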