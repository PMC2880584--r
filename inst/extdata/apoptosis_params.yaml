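# Rate constants for the apoptosis fixture, produced by
# bistable_parameter_search(apoptosis, retained = "C3a", seed = 1,
# n_draws = 500) with mechanistic range priors (complex dissociation and
# in-complex turnover k5, k7, k14 drawn from [1e-3, 0.1]; the matching
# binding/turnover constants k4, k6, k13 from [0.1, 10]; all others from
# the default [0.01, 10]); accepted at draw 4. The window in the conserved
# total C8* (et = C8a + C8aC3 + C8aBAR + C8aC3BAR) was verified by
# scan_conserved_total over [1, 1000] (fold points rounded outward).
rates:
  k1: 2.2
  k2: 0.46
  k3: 0.39
  k4: 3.8
  k5: 0.0011
  k6: 0.9
  k7: 0.029
  k8: 1.2
  k9: 0.27
  k10: 3.8
  kd: 0.21
  k12: 0.054
  k13: 0.14
  k14: 0.0016
retain: C3a
search_seed: 1
search_draw: 4
witness_total: 90
window:
  lo: 48.6
  hi: 169.44
known:
  s: 7
  c: 12
  r: 14
  rank: 6
  n_conservation: 1
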