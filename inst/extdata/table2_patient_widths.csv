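patient,width_reflex_bm,width_reflex_am,width_nonreflex_bm,width_nonreflex_am
1,0.115,0.173,0.137,0.141
2,0.058,0.141,0.065,0.118
3,0.362,0.301,0.393,0.455
4,0.158,0.133,0.178,0.106
5,0.120,0.149,0.203,NaN
6,0.213,0.109,0.125,0.110
7,0.092,0.134,0.103,0.138
8,0.262,0.229,0.160,0.124
9,0.133,0.250,0.176,0.392
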