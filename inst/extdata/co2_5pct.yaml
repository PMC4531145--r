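# 5% CO2 inhalation from t = 5 to 35 min, 1 h horizon
duration: 60
sampling: 0.5
overrides:
  - target: FCOI
    value: 0.05
    window: [5, 35]
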