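seed: 1
input: ~
synthetic:
  n_taxa: 30
  n_modules: 3
  p_within: 0.25
  p_between: 0.01
  neg_frac: 0.3
  corr_strength: 0.8
  groups:
  - control
  - cancer
  timepoints:
  - 16dpi
  - 22dpi
  n_samples_per_group: 8
  depth: 5000.0
  depth_dispersion: 0.05
  logmean_range:
  - 0.0
  - 3.0
  n_contaminants: 2
  n_controls: 4
  prevalence_in_controls: 1.0
  prevalence_in_samples: 0.1
thresholds:
  edge: 0.75
  core: 0.95
  keystone_abund: 0.35
  keystone_eig: 0.75
  min_total_reads: 10.0
  min_prevalence: 0.3
  loss_target: 0.8
  contaminant_score: 0.1
sparcc:
  n_resamples: 20
  prior: 1.0
  exclusion_threshold: 0.8
  max_exclusion_rounds: 10
robustness:
  n_boot: 100
  k_add:
  - 100
  - 300
  - 500
  - 700
  - 1000
  n_reps: 5
  attach_edges: 1
  rule: uniform
  trace_apl: no
diversity:
  n_perm: 999
  rarefy_depth: ~
diff_abundance:
  n_mc_instances: 128
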