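- id: 1
  var: peak_sharpness
  split: 5.9728375
  dir: lt
  left: 2
  right: 3
  pred: none
- id: 2
  var: .na.character
  split: .na.real
  dir: .na.character
  left: .na.integer
  right: .na.integer
  pred: none
- id: 3
  var: ratio
  split: 0.0488893
  dir: lt
  left: 6
  right: 7
  pred: tremor
- id: 6
  var: .na.character
  split: .na.real
  dir: .na.character
  left: .na.integer
  right: .na.integer
  pred: none
- id: 7
  var: .na.character
  split: .na.real
  dir: .na.character
  left: .na.integer
  right: .na.integer
  pred: tremor
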