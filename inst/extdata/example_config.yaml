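# example experiment configuration (times in ms, angles in rad)
seed: 1
stp: {U: 0.5, tau_u_ms: 650, tau_x_ms: 150, tau_s_ms: 100}
network: {n_neurons: 128, w_plus: 14, kernel_width_rad: 0.5}
noise: {kind: connectivity, p: 0.5, seed: 14}
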