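peak_cm1,x_low,N_low,x_half,N_half,x_full,N_full
630,0,40,2,40,40,40
728,0,40,11,40,40,40
1000,8,40,39,40,40,40
1218,0,40,29,40,40,40
1260,9,40,40,40,40,40
1315,0,40,0,40,40,40
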