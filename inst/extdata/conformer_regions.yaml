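# Conformer regions in (theta1, theta2) space, degrees in (-180, 180].
# Rectangles are left/bottom-closed, right/top-open (closed at +180).
# A  : symmetric site-1 homodimer (helix I-I), angles near zero
# Ap : flexible site-1 interfaces ringing A
# B  : site-2 homointerfaces (helices IV/V/VI)
# C  : site-1 x site-2 heterointerfaces
# Calibrated on the packaged synthetic receptor template geometry.
regions:
  - {label: A,  xmin: -25,  xmax: 25,   ymin: -25,  ymax: 25}
  - {label: Ap, xmin: -70,  xmax: -25,  ymin: -70,  ymax: 70}
  - {label: Ap, xmin: 25,   xmax: 70,   ymin: -70,  ymax: 70}
  - {label: Ap, xmin: -25,  xmax: 25,   ymin: -70,  ymax: -25}
  - {label: Ap, xmin: -25,  xmax: 25,   ymin: 25,   ymax: 70}
  - {label: B,  xmin: 110,  xmax: 180,  ymin: 110,  ymax: 180}
  - {label: B,  xmin: -130, xmax: -70,  ymin: -130, ymax: -70}
  - {label: C,  xmin: 110,  xmax: 180,  ymin: -70,  ymax: 110}
  - {label: C,  xmin: -180, xmax: -130, ymin: -130, ymax: -60}
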