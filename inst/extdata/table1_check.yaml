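# Moment-accuracy check: empirical vs closed-form mean/variance/skewness of g
# over the eight equiprobable size pairs (omit size_pairs for the default set).
task: moment_check
mu_delta: 0.5
tau2: 0.1
n_studies: 1000000
sampling: score
seed: 1
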