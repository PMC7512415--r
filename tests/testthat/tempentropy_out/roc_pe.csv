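"threshold","fpr","tpr"
Inf,0,0
0.990857147584531,0,0
0.986741756135668,0,0.0714285714285714
0.976736821459824,0,0.142857142857143
0.96552988481491,0,0.214285714285714
0.948422557919997,0,0.285714285714286
0.940445575065263,0,0.357142857142857
0.930119911591329,0,0.428571428571429
0.858901926677023,0,0.5
0.816071314423654,0,0.571428571428571
0.589824775559531,0,0.642857142857143
0.540219245959005,0,0.714285714285714
0.507508391090832,0.0625,0.714285714285714
0.503155189964877,0.125,0.714285714285714
0.489502082458871,0.125,0.785714285714286
0.469020733973588,0.1875,0.785714285714286
0.380328193151165,0.1875,0.857142857142857
0.346477331669324,0.25,0.857142857142857
0.294637800146366,0.3125,0.857142857142857
0.278274052208648,0.375,0.857142857142857
0.267713564089091,0.4375,0.857142857142857
0.163412012376689,0.5,0.857142857142857
0.153693620239752,0.5625,0.857142857142857
0.126970572532431,0.625,0.857142857142857
0.12177249454809,0.75,0.857142857142857
0.0820777456209637,0.75,0.928571428571429
0.0769118605378001,0.75,1
0.058538370102604,0.8125,1
0.00694323201693356,0.875,1
0.00222126354877365,0.9375,1
-Inf,1,1
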