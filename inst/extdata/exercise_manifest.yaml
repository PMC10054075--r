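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
- name: CVSD
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
- name: Mean NNI slope
  family: time_domain_slope
- name: Median NNI slope
  family: time_domain_slope
- name: SDNN slope
  family: time_domain_slope
- name: SDSD slope
  family: time_domain_slope
- name: RMSSD slope
  family: time_domain_slope
- name: CVNNI slope
  family: time_domain_slope
- name: CVSD slope
  family: time_domain_slope
- name: NNI 20 slope
  family: time_domain_slope
- name: PNNI 20 slope
  family: time_domain_slope
- name: NNI 50 slope
  family: time_domain_slope
- name: PNNI 50 slope
  family: time_domain_slope
- name: Range NNI slope
  family: time_domain_slope
- name: VLF
  family: frequency
- name: LF
  family: frequency
- name: HF
  family: frequency
- name: Total Power
  family: frequency
- name: VLF slope
  family: frequency_slope
- name: LF slope
  family: frequency_slope
- name: HF slope
  family: frequency_slope
- name: Total Power slope
  family: frequency_slope
- name: SD1
  family: nonlinear
- name: SD2
  family: nonlinear
- name: SD2/SD1
  family: nonlinear
- name: CSI
  family: nonlinear
- name: CVI
  family: nonlinear
- name: DFA Alpha 1
  family: nonlinear
- name: SD1 slope
  family: nonlinear_slope
- name: SD2 slope
  family: nonlinear_slope
- name: SD2/SD1 slope
  family: nonlinear_slope
- name: CSI slope
  family: nonlinear_slope
- name: CVI slope
  family: nonlinear_slope
- name: DFA Alpha 1 slope
  family: nonlinear_slope
- name: DFA Slope 60
  family: dfa_window
- name: DFA Slope 120
  family: dfa_window
- name: DFA Slope 180
  family: dfa_window
- name: Ins DFA Slope 60
  family: dfa_window
- name: Ins DFA Slope 120
  family: dfa_window
- name: Ins DFA Slope 180
  family: dfa_window
- name: SlopeSp25
  family: speed_quartile
- name: SlopeSp50
  family: speed_quartile
- name: SlopeSp75
  family: speed_quartile
- name: SlopeSp100
  family: speed_quartile
- name: RSp25
  family: speed_quartile
- name: RSp50
  family: speed_quartile
- name: RSp75
  family: speed_quartile
- name: RSp100
  family: speed_quartile
- name: TimeSp25
  family: speed_quartile
- name: TimeSp50
  family: speed_quartile
- name: TimeSp75
  family: speed_quartile
- name: TimeSp100
  family: speed_quartile
- name: RT25
  family: time_quartile
- name: RT50
  family: time_quartile
- name: RT75
  family: time_quartile
- name: RT100
  family: time_quartile
- name: SlopeT25
  family: time_quartile
- name: SlopeT50
  family: time_quartile
- name: SlopeT75
  family: time_quartile
- name: SlopeT100
  family: time_quartile
- name: TimeHR25
  family: hr_quartile
- name: TimeHR50
  family: hr_quartile
- name: TimeHR75
  family: hr_quartile
- name: TimeHR100
  family: hr_quartile
- name: HR MAX 25
  family: hr_quartile
- name: HR MAX 50
  family: hr_quartile
- name: HR MAX 75
  family: hr_quartile
- name: HR MAX 100
  family: hr_quartile
- name: DurationHR60
  family: hr_zone
- name: DurationHR70
  family: hr_zone
- name: DurationHR80
  family: hr_zone
- name: DurationHR90
  family: hr_zone
- name: DurationHR100
  family: hr_zone
- name: DurationSp20
  family: speed_zone
- name: DurationSp40
  family: speed_zone
- name: DurationSp60
  family: speed_zone
- name: DurationSp80
  family: speed_zone
- name: DurationSp100
  family: speed_zone
- name: HR Reserve
  family: session
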