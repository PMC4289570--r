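{
  "trial_label": "GENEVA-CRVO",
  "population": "CRVO",
  "treatment_name": "dexamethasone",
  "time_point": 1,
  "scheme_name": "geneva",
  "n_treatment": 136,
  "n_control": 147,
  "mean_treatment": 7.2,
  "mean_control": 0.4,
  "sd_treatment": 10.721,
  "sd_control": 10.721,
  "extra_ranges": [
    {"label": "Gain >=10 letters", "lower": 10, "upper": 30,
     "prob_treatment": 0.456, "prob_control": 0.122}
  ],
  "rr_reported": [
    {"label": "Gain >=15 letters", "rr": 3.13, "lower": 1.59, "upper": 6.19},
    {"label": "Gain >=5 and <15 letters", "rr": 1.68, "lower": 1.19, "upper": 2.38},
    {"label": "Loss <5 letters and gain <5 letters", "rr": 0.62, "lower": 0.46, "upper": 0.85},
    {"label": "Loss >=5 and <15 letters", "rr": 0.27, "lower": 0.10, "upper": 0.70},
    {"label": "Loss >=15 letters", "rr": 0.54, "lower": 0.19, "upper": 1.54},
    {"label": "Gain >=10 letters", "rr": 3.74, "lower": 2.33, "upper": 5.96}
  ],
  "source": "Published month-1 categorical BCVA change, CRVO dexamethasone trial; SDs back-calculated from reported confidence limits on change"
}
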