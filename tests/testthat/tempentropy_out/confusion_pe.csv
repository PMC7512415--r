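"model","class0_correct_pct","class1_correct_pct","total_pct","threshold"
"pe",87.5,78.5714285714286,83.3333333333333,0.5
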