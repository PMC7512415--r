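id,apen,pe,sampen,class
1,0.375369,8.173881,0.259592,0
2,0.355621,7.354433,0.166436,0
3,0.427184,8.233846,0.305818,0
4,0.328920,8.437123,0.133882,0
5,0.742144,8.523112,0.589070,0
6,0.444839,8.458743,0.312369,0
7,0.444839,8.253519,0.331899,0
8,0.465783,8.422755,0.327447,0
9,0.649292,8.562641,0.411671,0
10,0.334577,8.737973,0.238648,0
11,0.404367,7.944453,0.282284,0
12,0.686112,8.683103,0.500797,0
13,0.211678,7.045437,0.125658,0
14,0.635363,8.702552,0.488307,0
15,0.375369,8.173881,0.259592,0
16,0.646044,8.023478,0.333306,0
17,0.132585,9.096728,0.102007,1
18,0.409274,9.480602,0.292390,1
19,0.083815,8.160992,0.074664,1
20,0.457642,8.042545,0.290163,1
21,0.143293,9.393343,0.090606,1
22,0.354052,9.858080,0.256855,1
23,0.407061,9.594236,0.275580,1
24,0.314689,9.703521,0.243019,1
25,0.269602,8.792517,0.161793,1
26,0.027989,9.439494,0.006332,1
27,0.376410,8.697850,0.230783,1
28,0.241392,9.959548,0.172143,1
29,0.053292,9.182114,0.011505,1
30,0.279302,8.660942,0.201991,1
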