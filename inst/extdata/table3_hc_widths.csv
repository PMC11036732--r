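participant,width_reflex_s,width_nonreflex_s
1,0.088,0.125
2,NaN,NaN
3,0.099,NaN
4,0.194,0.205
5,NaN,0.071
6,0.174,0.181
7,0.104,NaN
8,0.151,0.151
9,0.103,0.127
10,0.098,NaN
11,0.156,0.154
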