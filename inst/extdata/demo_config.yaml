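# clonarch demo configuration: a small cohort with default study-like
# generative parameters. All keys are sim_config() arguments.
seed: 42
n_patients: 60
mean_depth: 100
contamination_rho: 0.05
error_rate_eps: 0.001
n_colonies: 40
colony_dropout: 0.02
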