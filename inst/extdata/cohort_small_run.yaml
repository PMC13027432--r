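# Example end-to-end pipeline configuration on the small synthetic preset.
# Run with:
#   cfg <- read_pipeline_config(system.file("extdata", "cohort_small_run.yaml",
#                                           package = "ptmatlas"))
#   run_pipeline(cfg, out_dir = "ptm_run")
input:
  preset: cohort_small
predominant_threshold: 0.60
sensitivity_thresholds: [0.50, 0.60, 0.70]
half_window: 7
min_neighbors: 5
crosstalk_mode: residue
sparsity_threshold: 0.01
k_range: [2, 10]
cluster_method: ward
q_threshold: 0.05
seed: 1
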