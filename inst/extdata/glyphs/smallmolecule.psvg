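<svg xmlns="http://www.w3.org/2000/svg" xmlns:parametric="https://parametric-svg.github.io/v0.2" parametric:type="SmallMolecule" parametric:defaults="width=8;height=8" viewBox="0 -8 8 8">
  <path id="body" d="M 0 -4 A 4 4 0 0 1 8 -4 A 4 4 0 0 1 0 -4 Z" parametric:d="M 0 {-height/2} A {width/2} {height/2} 0 0 1 {width} {-height/2} A {width/2} {height/2} 0 0 1 0 {-height/2} Z" style="fill:white;stroke:black;stroke-width:1"/>
  <path id="baseline" d="M 0 0 L 8 0" parametric:d="M 0 0 L {width} 0" style="fill:none;stroke:none"/>
  <path id="bounding-box" d="M 0 -8 L 8 -8 L 8 0 L 0 0 Z" parametric:d="M 0 {-height} L {width} {-height} L {width} 0 L 0 0 Z" style="fill:none;stroke:none"/>
</svg>
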