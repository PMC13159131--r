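# smtrack pipeline configuration (flat key-value; units in the manual)
dt: 0.1
sigma_loc: 0.03
pixel_size: 0.107
psf_sigma: 0.12
threshold_factor: 5
r_max: 2.5
gap_max: 1
min_len: 20
n_fit: 4
alpha_lags_max: 10
confined_max: 0.7
directed_min: 1.3
min_traj: 1000
seed: 1
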