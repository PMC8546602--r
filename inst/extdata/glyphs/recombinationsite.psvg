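<svg xmlns="http://www.w3.org/2000/svg" xmlns:parametric="https://parametric-svg.github.io/v0.2" parametric:type="RecombinationSite" parametric:defaults="width=10;height=10" viewBox="0 -10 10 10">
  <path id="triangle" d="M 0 0 L 10 0 L 5 -10 Z" parametric:d="M 0 0 L {width} 0 L {width/2} {-height} Z" style="fill:orange;stroke:black;stroke-width:1"/>
  <path id="baseline" d="M 0 0 L 10 0" parametric:d="M 0 0 L {width} 0" style="fill:none;stroke:none"/>
  <path id="bounding-box" d="M 0 -10 L 10 -10 L 10 0 L 0 0 Z" parametric:d="M 0 {-height} L {width} {-height} L {width} 0 L 0 0 Z" style="fill:none;stroke:none"/>
</svg>
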