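# Receptor-induced apoptosis core: caspase-8-dependent activation of
# caspase 3 with inhibition by BAR. Species (x1..x7 order):
#   C8a      activated caspase 8 (C8*)
#   C3       procaspase 3
#   C8aC3    C8*:C3 complex
#   C3a      activated (cleaved) caspase 3 (C3*)
#   BAR      bifunctional apoptosis regulator (inhibitor)
#   C8aBAR   C8*:BAR complex
#   C8aC3BAR C8*:C3:BAR ternary complex
# This reaction list is a SYNTHETIC RECONSTRUCTION built to the published
# constraints (7 species, 14 mass-action reactions, conserved total C8* =
# C8a + C8aC3 + C8aBAR + C8aC3BAR, BAR degradation governed by kd); the
# original reaction list is not recoverable from the available text.
species: C8a C3 C8aC3 C3a BAR C8aBAR C8aC3BAR
C8a + C3 <-> C8aC3 ; k1, k2
C8aC3 -> C8a + C3a ; k3
C8a + BAR <-> C8aBAR ; k4, k5
C8aC3 + BAR <-> C8aC3BAR ; k6, k7
0 -> C3 ; k8
C3 -> 0 ; k9
0 -> BAR ; k10
BAR -> 0 ; kd
C3a -> 0 ; k12
C8aBAR -> C8a ; k13
C8aC3BAR -> C8aC3 ; k14
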