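study_id,g,n1,n2
study_1,-0.1093,10,20
study_2,-0.2354,5,5
study_3,-0.086,10,10
study_4,0.4485,20,20
study_5,-0.1734,15,15
study_6,0.118,5,15
study_7,-0.0899,20,20
study_8,0.74,5,15
study_9,0.2599,10,20
study_10,0.8982,5,5
study_11,0.5783,10,10
study_12,0.5716,10,30
study_13,-0.3503,15,25
study_14,1.1004,15,15
study_15,0.4196,10,10
study_16,1.4831,10,20
study_17,-0.0976,10,10
study_18,0.764,10,20
study_19,1.1599,5,5
study_20,0.5151,20,20
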