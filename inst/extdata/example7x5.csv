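A,B,C,D,E
0,0,0,2,0
0,1,0,2,0
0,2,0,2,2
0,3,1,2,0
4,1,1,1,4
4,3,1,1,2
0,0,1,2,0
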