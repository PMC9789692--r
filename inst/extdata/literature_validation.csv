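source,body_weight,egg_mass,observed_intake
study_A_bw170,0.170,10.72,289
study_A_bw180,0.180,10.72,289
study_A_bw190,0.190,10.72,289
study_B_bw170,0.170,11.13,302
study_B_bw180,0.180,11.13,302
study_B_bw190,0.190,11.13,302
study_C,0.181,9.75,259
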