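# fixed hyperventilation at three times normal alveolar ventilation, 48 h
duration: 2880
sampling: 5
clamps:
  - target: VI
    value: 15
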