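<svg xmlns="http://www.w3.org/2000/svg" xmlns:parametric="https://parametric-svg.github.io/v0.2" parametric:type="CDS" parametric:defaults="width=30;height=15;arrowhead_width=10" viewBox="0 -7.5 30 15">
  <path id="body" d="M 0 -7.5 L 20 -7.5 L 30 0 L 20 7.5 L 0 7.5 Z" parametric:d="M 0 {-height/2} L {width - arrowhead_width} {-height/2} L {width} 0 L {width - arrowhead_width} {height/2} L 0 {height/2} Z" style="fill:green;stroke:black;stroke-width:1"/>
  <path id="baseline" d="M 0 0 L 30 0" parametric:d="M 0 0 L {width} 0" style="fill:none;stroke:none"/>
  <path id="bounding-box" d="M 0 -7.5 L 30 -7.5 L 30 7.5 L 0 7.5 Z" parametric:d="M 0 {-height/2} L {width} {-height/2} L {width} {height/2} L 0 {height/2} Z" style="fill:none;stroke:none"/>
</svg>
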