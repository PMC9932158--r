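# Default workflow configuration.  Fractions unless noted.
ci_level: 0.95
mosaic_floor: 0.003          # smallest p_hat called as parental mosaicism
constitutional_band: [0.45, 0.55]
phasing_alpha: 0.01
phasing_min_depth: 10        # phase-set SNPs kept at depth > 10
conservative: true           # report sperm risk at the CI upper bound
force_phase: false
reporting_floor: 0.001       # cohort count of families below 0.1%
max_discordant: 0
priors:                      # category prevalence, sums to 1
  A: 0.71
  B: 0.03
  C: 0.04
  D: 0.15
  E: 0.02
  F: 0.03
  G: 0.02
vaf_model:
  # synthetic reference panel of confined-gonadal sperm VAFs (percent);
  # replace with an empirical panel when available
  vafs: [2.8, 3.1, 3.3, 3.4, 3.5, 3.7, 3.8, 3.9, 4.0, 4.1, 4.2, 4.3, 4.4, 4.6, 5.0, 8.5]
  mixed_mean: 8.0
  n_boot: 20000
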