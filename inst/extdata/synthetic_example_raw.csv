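study_id,mean1,sd1,n1,mean2,sd2,n2
trial_1,10.61,1.92,12,9.35,2.1,12
trial_2,10.74,2.18,20,9.63,1.99,18
trial_3,10.54,2.21,15,10.46,2.01,15
trial_4,10.72,2.18,30,10.38,2.13,28
trial_5,10.32,2.01,10,8.75,1.82,12
trial_6,10.56,1.86,25,8.48,2.07,25
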