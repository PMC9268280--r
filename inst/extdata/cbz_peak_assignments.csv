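wavenumber_cm1,vibrational_description
630,ring stretching and C-C bending
728,C-C bending and C-O-CH3 bending
1000,C-N bending and C-C bending and C-O-CH3 stretching
1218,"C-C stretch, C-C bending and N-H bending"
1260,C-H bending and N-H bending
1315,ring stretching
1370,C-N stretch
1460,N-H bending and C-H bending
1523,N-H bending and C-N stretch
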