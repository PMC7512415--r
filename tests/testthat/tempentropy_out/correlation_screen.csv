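"measure_a","measure_b","r","p"
"apen","pe",-0.236563436692767,0.208170985569086
"apen","sampen",0.960116134855148,4.94364519203778e-17
"pe","sampen",-0.134201833594485,0.479548793981266
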