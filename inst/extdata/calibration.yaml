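gait_model:
  intercept: 1.11116778204364
  coef:
    rom_deg: -1.063333189753459
    cadence: 0.000224601705557
    swing_cv: -0.00186990521195
  center:
    rom_deg: 36.177018387922445
    cadence: 102.858176354886524
    swing_cv: 0.060538868506533
  scale:
    rom_deg: 8.802329791989035
    cadence: 9.732523647494043
    swing_cv: 0.023604780463501
dysk_scale: 0.368795386725733
brady_normative_dps: 84.427480887677689
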