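# Demo pipeline configuration: a small simulated study.
# Run with:  run_all(read_pipeline_config(system.file("extdata",
#            "demo_config.yaml", package = "lobesym")))
seed: 1
n_perm_anova: 99
n_perm_signal: 499
n_perm_pls: 99
n_lobulate: 5
simulate:
  n_species: 6
  n_individuals: 10
  n_replicates: 2
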