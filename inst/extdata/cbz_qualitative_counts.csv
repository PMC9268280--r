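concentration,x,N
0.000,0,10
0.050,0,50
0.100,40,50
0.500,39,40
1.000,40,40
2.500,40,40
5.000,40,40
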