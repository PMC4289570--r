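category_label,lower,upper,prob_treatment,prob_control
Gain >=20 letters,20,30,0.191,0.038
Gain >=10 and <20 letters,10,19,0.313,0.197
Loss <10 letters and gain <10 letters,-9,9,0.489,0.705
Loss >=10 and <20 letters,-19,-10,0.008,0.045
Loss >=20 letters,-30,-20,0.000,0.015
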