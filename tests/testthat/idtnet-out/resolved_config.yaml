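seed: 1
out_dir: idtnet-out
n_units: 500
gamma: 1.6
k_min: 1
k_max: .na
temperature: 9.0
coupling_J: 1.0
rule: metropolis
schedule: random-site
burn_in_sweeps: 1000
analytic_epsilon_bits: 0.001
c_eff: 1.0
uniqueness_mode: upper-bound-1
neighbor_magnetization: equilibrium
n_realizations: 6
n_series: 5000
tau_max_sweeps: 15
n_prior_sweeps: 2000
empirical_epsilon_bits: 0.01
trajectory_layout: long
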