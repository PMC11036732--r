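tap,group,category,value
1,iPD_before,reflex,0.888
2,iPD_before,reflex,1
3,iPD_before,reflex,1
4,iPD_before,reflex,1
5,iPD_before,reflex,0.888
6,iPD_before,reflex,1
7,iPD_before,reflex,0.888
8,iPD_before,reflex,0.888
1,iPD_after,reflex,1
2,iPD_after,reflex,1
3,iPD_after,reflex,0.888
4,iPD_after,reflex,1
5,iPD_after,reflex,1
6,iPD_after,reflex,0.777
7,iPD_after,reflex,1
8,iPD_after,reflex,0.888
1,HC,reflex,0.727
2,HC,reflex,0.545
3,HC,reflex,0.454
4,HC,reflex,0.454
5,HC,reflex,0.181
6,HC,reflex,0.272
7,HC,reflex,0.181
8,HC,reflex,0.181
1,iPD_before,non_reflex,0.666
2,iPD_before,non_reflex,1
3,iPD_before,non_reflex,1.333
4,iPD_before,non_reflex,1.444
5,iPD_before,non_reflex,0.888
6,iPD_before,non_reflex,1.444
7,iPD_before,non_reflex,1.666
8,iPD_before,non_reflex,0.888
1,iPD_after,non_reflex,2.555
2,iPD_after,non_reflex,1.222
3,iPD_after,non_reflex,1.777
4,iPD_after,non_reflex,0.777
5,iPD_after,non_reflex,0.666
6,iPD_after,non_reflex,0.444
7,iPD_after,non_reflex,0.555
8,iPD_after,non_reflex,0.666
1,HC,non_reflex,0.700
2,HC,non_reflex,0.500
3,HC,non_reflex,0.400
4,HC,non_reflex,0.300
5,HC,non_reflex,0.300
6,HC,non_reflex,0.200
7,HC,non_reflex,0.200
8,HC,non_reflex,0.100
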