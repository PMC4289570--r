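{
  "trial_label": "BRAVO",
  "population": "BRVO",
  "treatment_name": "ranibizumab",
  "time_point": 1,
  "scheme_name": "ranibizumab",
  "n_treatment": 131,
  "n_control": 132,
  "rr_reported": [
    {"label": "Gain >=20 letters", "rr": 5.04, "lower": 1.99, "upper": 12.76},
    {"label": "Gain >=10 and <20 letters", "rr": 1.59, "lower": 1.04, "upper": 2.44},
    {"label": "Loss <10 letters and gain <10 letters", "rr": 0.69, "lower": 0.56, "upper": 0.85},
    {"label": "Loss >=10 and <20 letters", "rr": 0.17, "lower": 0.02, "upper": 1.38},
    {"label": "Loss >=20 letters", "rr": 0.00, "lower": 0.00, "upper": 0.00}
  ],
  "source": "Published month-1 categorical BCVA change, BRVO ranibizumab trial"
}
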