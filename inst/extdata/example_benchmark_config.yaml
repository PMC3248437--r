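# Example benchmark configuration. Keys mirror benchmark_config();
# omitted keys use the package defaults.
n_genes: 40
edge_densities: [0.01, 0.02]
sample_sizes: [50, 200]
n_datasets: 10
estimators: [empirical, miller_madow, shrink, schurmann_grassberger]
discretizations: [equal_frequency, equal_width, global_equal_width]
noise_sd: 0.05
interaction_strength: 1.0
alpha: 0.05
correction: benjamini_hochberg
n_permutations: 2000
d_max: 4
seed: 1
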