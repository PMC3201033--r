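# Enzyme kinetics motif: S + E <-> CS -> CP <-> P + E
# Binding steps r1 and r3 are fast; the conversion r2 is slow.
[species]
S = 1
E = 1
P = 0
CS = 0
CP = 0

[parameters]
k1 = 1000
km1 = 2000
k2 = 1
k3 = 3000
km3 = 1000

[reactions]
r1: S + E <-> CS : k1*S*E - km1*CS
r2: CS -> CP : k2
r3: CP <-> P + E : km3*CP - k3*P*E
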