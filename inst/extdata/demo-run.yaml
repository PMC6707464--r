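# Demo run: simulate a small call set over a deep-split genealogy (a D0-like
# clade splitting from D at 71,400 years ago, E diverging at 73,200, two
# outgroup samples at the root), filter it, polarize against the outgroup,
# date the two splits with the calibrated rho statistic, place the D0-like
# clade, and derive the migration-window report.
seed: 20260925
data:
  sim:
    newick: "((((D0_1:2500,D0_2:2500,D0_3:2500):68900,(D_1:2500,D_2:2500):68900):1800,(E_1:2500,E_2:2500):70700):26800,og1:100000,og2:100000);"
    region_length: 200000
    recurrence_prob: 0.002
    coverage:
      mean_dp: 16
      error_rate: 0.002
      missing_rate: 0.05
filter:
  enabled: true
  remove_duplicates: false
polarize:
  outgroup: [og1, og2]
clock:
  mu_point: 7.6e-10
  mu_hpd_low: 6.7e-10
  mu_hpd_high: 8.6e-10
date:
  denominator: callable_length_proxy
  nodes:
    - name: D0_D_split
      clade_a: [D0_1, D0_2, D0_3]
      clade_b: [D_1, D_2]
    - name: D_E_split
      clade_a: [D0_1, D0_2, D0_3, D_1, D_2]
      clade_b: [E_1, E_2]
place:
  query: [D0_1, D0_2, D0_3]
  references:
    D: [D_1, D_2]
    E: [E_1, E_2]
scenario:
  speedup: 0.14
  fossil: [43210, 46880]
  generations: [232, 430]
  generation_time: 29
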