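concentration,x,N
0.50,7,40
2.50,34,40
5.00,40,40
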