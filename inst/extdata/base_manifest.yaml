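features:
- name: Age
  family: metadata
- name: Gender
  family: metadata
- name: Height
  family: metadata
- name: Weight
  family: metadata
- name: BMI
  family: metadata
- name: Protocol Type
  family: metadata
- name: Max. Speed
  family: session
- name: Ex. Duration
  family: session
- name: Max. HR
  family: session
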