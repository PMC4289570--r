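category_label,lower,upper,prob_treatment,prob_control
Gain >=15 letters,15,30,0.213,0.079
Gain >=5 and <15 letters,5,14,0.474,0.369
Loss <5 letters and gain <5 letters,-4,4,0.258,0.441
Loss >=5 and <15 letters,-14,-5,0.055,0.097
Loss >=15 letters,-30,-15,0.000,0.014
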