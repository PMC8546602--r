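<svg xmlns="http://www.w3.org/2000/svg" xmlns:parametric="https://parametric-svg.github.io/v0.2" parametric:type="Protein" parametric:defaults="width=14;height=14" viewBox="0 -14 14 14">
  <path id="body" d="M 0 -7 A 7 7 0 0 1 14 -7 A 7 7 0 0 1 0 -7 Z" parametric:d="M 0 {-height/2} A {width/2} {height/2} 0 0 1 {width} {-height/2} A {width/2} {height/2} 0 0 1 0 {-height/2} Z" style="fill:lightgray;stroke:black;stroke-width:1"/>
  <path id="baseline" d="M 0 0 L 14 0" parametric:d="M 0 0 L {width} 0" style="fill:none;stroke:none"/>
  <path id="bounding-box" d="M 0 -14 L 14 -14 L 14 0 L 0 0 Z" parametric:d="M 0 {-height} L {width} {-height} L {width} 0 L 0 0 Z" style="fill:none;stroke:none"/>
</svg>
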