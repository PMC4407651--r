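# Small end-to-end demonstration configuration for run_pipeline():
# a 32^3 sand-like medium drained over the default seven-potential
# schedule, two REV subsamples, two dyadic levels, z-direction solves.
texture: sand_like
grid_shape: [32, 32, 32]
target_porosity: 0.45
n_subsamples: 2
j_max: 1
directions: 3
solver_tol: 1.0e-8
seed: 1
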