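# Glucose transport across the yeast cell membrane by a carrier enzyme,
# with G6P inhibition on the inner face. Binding reactions (r1-r4) are fast;
# the translocation exchanges (ra, rb) are slow.
# Parameter values are synthetic placeholders (see package documentation).
[species]
Glce = 0.1
Glci = 0
EG6Pi = 0
EGlcG6Pi = 0
G6Pi = 0.05
EGlce = 0
EGlci = 0
Ee = 0.005
Ei = 0.005

[parameters]
k1 = 1e5
km1 = 1e3
k2 = 1e5
km2 = 1e3
k3 = 1e5
km3 = 1e3
k4 = 1e5
km4 = 1e3
alpha = 1
beta = 1

[reactions]
r1: Ee + Glce <-> EGlce : k1, km1
r2: Ei + Glci <-> EGlci : k2, km2
r3: EGlci + G6Pi <-> EGlcG6Pi : k3, km3
r4: Ei + G6Pi <-> EG6Pi : k4, km4
ra: EGlci -> EGlce : alpha*(EGlci - EGlce)
rb: Ei -> Ee : beta*(Ei - Ee)
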