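"model","deviance","aic"
"pe",24.0312597740708,28.0312597740708
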