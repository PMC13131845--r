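# Example configuration for the `axomito run` command line.
# Any field of sim_params() may appear here; unlisted fields keep the
# reference defaults (Table of model parameters in the methods vignette).
phi_fraction: 0.3     # density as a fraction of phi_max = pi/sqrt(18)
n_chain: 5            # beads per mitochondrion
kb_mito: 1.0e-19      # chain bending rigidity, N m^2
k_fission: 0.0        # 1/s
k_fusion: 0.0         # 1/s
mode: fixed_axon      # fixed_axon | deformable
t_end: 30             # s
seed: 1
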