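# Demo configuration for run_pipeline(); identical to demo_config().
seed: 42
genotypes:
  n: 24
  length: 250
  min_dist: 5
reads:
  per_sample: 1200
  pcr_error_rate: 1.0e-5
  pcr_cycles: 30
  seq_error_rate: 1.0e-3
  chimera_rate: 0.005
  fwd_len: 180
  rev_len: 180
  n_templates: 8192
  pool_cap: 16384
metacommunity:
  n_sites: 8
  individuals_per_site: 1000
  niche_weight: 0.5
  niche_breadth: 0.5
denoise:
  alpha: 1.0e-20
  max_ee: 0.5
  min_overlap: 30
  max_parent_dist: 10
  min_count: 2
  min_parent_skew: 2
rarefy:
  depth: 800
nullmodel:
  n_reps: 200
  metric: bray
bnti:
  n_reps: 199
geochem:
  n_methanotroph_otus: 3
  total_cells_per_ml: 6.1e6
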