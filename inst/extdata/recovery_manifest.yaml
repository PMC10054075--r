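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
- name: Min HR
  family: session
- name: Mean HR
  family: session
- name: Std. HR
  family: session
- name: Mean NNI
  family: time_domain
- name: Median NNI
  family: time_domain
- name: SDNN
  family: time_domain
- name: SDSD
  family: time_domain
- name: RMSSD
  family: time_domain
- name: CVNNI
  family: time_domain
- name: NNI 20
  family: time_domain
- name: PNNI 20
  family: time_domain
- name: NNI 50
  family: time_domain
- name: PNNI 50
  family: time_domain
- name: Range NNI
  family: time_domain
- name: SD1
  family: nonlinear
- name: SD2
  family: nonlinear
- name: DFA Slope 60
  family: dfa_window
- name: DFA Slope 120
  family: dfa_window
- name: DFA Slope 180
  family: dfa_window
- name: Ins DFA Slope 120
  family: dfa_window
- name: Ins DFA Slope 180
  family: dfa_window
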