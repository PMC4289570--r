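{
  "trial_label": "CRUISE",
  "population": "CRVO",
  "treatment_name": "ranibizumab",
  "time_point": 1,
  "scheme_name": "ranibizumab",
  "n_treatment": 130,
  "n_control": 130,
  "rr_reported": [
    {"label": "Gain >=20 letters", "rr": 4.25, "lower": 1.47, "upper": 12.29},
    {"label": "Gain >=10 and <20 letters", "rr": 3.31, "lower": 1.87, "upper": 5.85},
    {"label": "Loss <10 letters and gain <10 letters", "rr": 0.69, "lower": 0.57, "upper": 0.83},
    {"label": "Loss >=10 and <20 letters", "rr": 0.20, "lower": 0.04, "upper": 0.90},
    {"label": "Loss >=20 letters", "rr": 0.00, "lower": 0.00, "upper": 0.00}
  ],
  "source": "Published month-1 categorical BCVA change, CRVO ranibizumab trial"
}
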