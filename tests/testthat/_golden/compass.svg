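<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" width="600" height="600" viewBox="0 0 600 600">
<title>compass R001 t1</title>
<path id="sector-life" d="M300.000,60.000 A240.000,240.000 0 0,1 487.640,150.362 L364.548,248.525 A82.560,82.560 0 0,0 300.000,217.440 Z" fill="#FF7F0E" stroke="#FFFFFF" stroke-width="2"/>
<path id="marker-life" d="M300.000,217.440 A82.560,82.560 0 0,1 364.548,248.525 L337.528,270.072 A48.000,48.000 0 0,0 300.000,252.000 Z" fill="#FF7F0E" stroke="#FFFFFF" stroke-width="1"/>
<text x="417.149" y="60.738" font-size="12" font-family="sans-serif" text-anchor="middle">Life</text>
<path id="sector-cognition" d="M487.640,150.362 A240.000,240.000 0 0,1 533.983,353.405 L380.490,318.371 A82.560,82.560 0 0,0 364.548,248.525 Z" fill="#FF7F0E" stroke="#FFFFFF" stroke-width="2"/>
<path id="marker-cognition" d="M364.548,248.525 A82.560,82.560 0 0,1 380.490,318.371 L346.797,310.681 A48.000,48.000 0 0,0 337.528,270.072 Z" fill="#FF7F0E" stroke="#FFFFFF" stroke-width="1"/>
<text x="563.231" y="243.919" font-size="12" font-family="sans-serif" text-anchor="middle">Cognition</text>
<path id="sector-emotion" d="M533.983,353.405 A240.000,240.000 0 0,1 404.132,516.233 L335.821,374.384 A82.560,82.560 0 0,0 380.490,318.371 Z" fill="#FF7F0E" stroke="#FFFFFF" stroke-width="2"/>
<path id="marker-emotion" d="M380.490,318.371 A82.560,82.560 0 0,1 335.821,374.384 L320.826,343.247 A48.000,48.000 0 0,0 346.797,310.681 Z" fill="#FF7F0E" stroke="#FFFFFF" stroke-width="1"/>
<text x="511.095" y="472.342" font-size="12" font-family="sans-serif" text-anchor="middle">Emotion</text>
<path id="sector-fatigue" d="M404.132,516.233 A240.000,240.000 0 0,1 195.868,516.233 L264.179,374.384 A82.560,82.560 0 0,0 335.821,374.384 Z" fill="#FF7F0E" stroke="#FFFFFF" stroke-width="2"/>
<path id="marker-fatigue" d="M335.821,374.384 A82.560,82.560 0 0,1 264.179,374.384 L279.174,343.247 A48.000,48.000 0 0,0 320.826,343.247 Z" fill="#FF7F0E" stroke="#FFFFFF" stroke-width="1"/>
<text x="300.000" y="574.000" font-size="12" font-family="sans-serif" text-anchor="middle">Fatigue</text>
<path id="sector-sexuality_continence" d="M195.868,516.233 A240.000,240.000 0 0,1 66.017,353.405 L219.510,318.371 A82.560,82.560 0 0,0 264.179,374.384 Z" fill="#FF7F0E" stroke="#FFFFFF" stroke-width="2"/>
<path id="marker-sexuality_continence" d="M264.179,374.384 A82.560,82.560 0 0,1 219.510,318.371 L253.203,310.681 A48.000,48.000 0 0,0 279.174,343.247 Z" fill="#D62728" stroke="#FFFFFF" stroke-width="1"/>
<text x="88.905" y="472.342" font-size="12" font-family="sans-serif" text-anchor="middle">Sexuality and continence</text>
<path id="sector-sensory" d="M66.017,353.405 A240.000,240.000 0 0,1 112.360,150.362 L235.452,248.525 A82.560,82.560 0 0,0 219.510,318.371 Z" fill="#FF7F0E" stroke="#FFFFFF" stroke-width="2"/>
<path id="marker-sensory" d="M219.510,318.371 A82.560,82.560 0 0,1 235.452,248.525 L262.472,270.072 A48.000,48.000 0 0,0 253.203,310.681 Z" fill="#FF7F0E" stroke="#FFFFFF" stroke-width="1"/>
<text x="36.769" y="243.919" font-size="12" font-family="sans-serif" text-anchor="middle">Sensory function</text>
<path id="sector-motor" d="M112.360,150.362 A240.000,240.000 0 0,1 300.000,60.000 L300.000,217.440 A82.560,82.560 0 0,0 235.452,248.525 Z" fill="#FF7F0E" stroke="#FFFFFF" stroke-width="2"/>
<path id="marker-motor" d="M235.452,248.525 A82.560,82.560 0 0,1 300.000,217.440 L300.000,252.000 A48.000,48.000 0 0,0 262.472,270.072 Z" fill="#FF7F0E" stroke="#FFFFFF" stroke-width="1"/>
<text x="182.851" y="60.738" font-size="12" font-family="sans-serif" text-anchor="middle">Motor function</text>
<rect id="legend-red" x="10.000" y="10.000" width="14" height="14" fill="#D62728"/>
<text x="30.000" y="21.000" font-size="11" font-family="sans-serif" text-anchor="start">0-30 worst</text>
<rect id="legend-orange" x="10.000" y="30.000" width="14" height="14" fill="#FF7F0E"/>
<text x="30.000" y="41.000" font-size="11" font-family="sans-serif" text-anchor="start">30-70</text>
<rect id="legend-green" x="10.000" y="50.000" width="14" height="14" fill="#2CA02C"/>
<text x="30.000" y="61.000" font-size="11" font-family="sans-serif" text-anchor="start">70-100 best</text>
<rect id="legend-missing" x="10.000" y="70.000" width="14" height="14" fill="#BFBFBF"/>
<text x="30.000" y="81.000" font-size="11" font-family="sans-serif" text-anchor="start">not scored</text>
</svg>
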