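# Estimator-performance grid: bias / variance / RMSE / coverage of the MM,
# DL and REML estimators across tau2 x k conditions, mu_delta fixed at 0.5.
task: grid
mu_delta: 0.5
tau2: [0.1, 0.3, 0.5, 0.7, 0.9]
k: [15, 30, 45]
n_reps: 2000
level: 0.95
seed: 1
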