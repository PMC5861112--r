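# Example run configuration: standard sweep conditions
gamma_ref: 0.2
t_ref: 20
rate_gamma: 0.015
rate_mus: 0.004
vs_model: constant
vs_value: 1500
compounding: false
depths: [5, 10, 15, 20, 25, 30]
temperatures: [5, 10, 15, 20, 25, 30, 35]
n_photons: 100000
seed: 1
scenario: both
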