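# Example ihcquant experiment configuration (flat key = value).
# Keys matching tissue_sim_params() fields configure the simulator, keys
# matching segmentation_params() the segmentation; the rest map onto
# experiment_config().

experiment = dosage
replicates = 3
n_cells = 300
seed = 1

# simulator
stromal_fraction = 0.15
background_od = 0.05
heterogeneity_cv = 0.3
noise_sd = 2

# segmentation
background_threshold = 0.2
avg_nuclear_size_px = 14
ring_width_px = 3
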