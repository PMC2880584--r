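# Rate constants for the Edelstein fixture, produced by
# bistable_parameter_search(edelstein, retained = "A", seed = 1,
# n_draws = 200); accepted at draw 2. The multistationarity window in the
# conserved total et = B + C was verified by scan_conserved_total over
# [1, 1000] (fold points rounded outward).
rates:
  k1: 6.8
  k2: 0.96
  k3: 0.77
  k4: 0.015
  k5: 0.041
  k6: 0.034
retain: A
search_seed: 1
search_draw: 2
witness_total: 100
window:
  lo: 39.77
  hi: 304.88
known:
  s: 3
  c: 5
  r: 6
  rank: 2
  n_conservation: 1
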