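"term","estimate","std_error","wald","df","p_value","lr_p","exp_b"
"(Intercept)",-32.2017863685041,12.0250639983737,7.17108939074846,1,0.00740877706995316,NA,1.03500362943586e-14
"pe",3.70372072361457,1.39492537800927,7.04976292039599,1,0.00792757431850205,2.99004592749803e-05,40.5980779199782
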