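# default pipeline thresholds; see ?pipeline_config
fdr_alpha: 0.01
expression_floor: 5
kmeans_k: 6
promoter_halfwidth: 3000
top_variance_k: 2000
pseudocount: 1
rng_seed: 1
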