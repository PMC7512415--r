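"model","deviance","null_deviance","r2_cox_snell","r2_nagelkerke","aic","n"
"pe",24.0312597740708,41.4553985588291,0.44055196110949,0.588276725076109,28.0312597740708,30
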