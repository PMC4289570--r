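category_label,lower,upper,prob_treatment,prob_control
Gain >=15 letters,15,30,0.213,0.068
Gain >=5 and <15 letters,5,14,0.412,0.245
Loss <5 letters and gain <5 letters,-4,4,0.301,0.483
Loss >=5 and <15 letters,-14,-5,0.037,0.136
Loss >=15 letters,-30,-15,0.037,0.068
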