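# Example pipeline configuration for `read_run_config()` /
# `Rscript inst/cli/accelcox.R pipeline --config example-run.yaml`.
# Omitted keys keep their defaults; `sim` is ignored when cohort_csv is set.
out_dir: accelcox-run
seed: 1
n_draws: 10000
plots: true
sim:
  n_participants: 2000
  baseline_hazard: 0.0024
  censor_time_years: 6.4
  seed: 1
spec_adjusted:
  k_vol: 10
  k_int: 10
spec_unadjusted:
  k_vol: 10
  k_int: 10
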