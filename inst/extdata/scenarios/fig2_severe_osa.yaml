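# Severe OSA validation pattern: four 40-s apneas separated by 10-s
# hyperventilation epochs (V_T = 1.0 L, b_r = 24/min); AHI = 72.
V_T: 0.5
V_D: 0.15
V_End: 2.3
b_r: 12
total_duration: 200
stabilization_time: 360
events:
  - {kind: apnea, start: 0,   duration: 40}
  - {kind: hyperventilation, start: 40,  duration: 10, V_T: 1.0, b_r: 24}
  - {kind: apnea, start: 50,  duration: 40}
  - {kind: hyperventilation, start: 90,  duration: 10, V_T: 1.0, b_r: 24}
  - {kind: apnea, start: 100, duration: 40}
  - {kind: hyperventilation, start: 140, duration: 10, V_T: 1.0, b_r: 24}
  - {kind: apnea, start: 150, duration: 40}
  - {kind: hyperventilation, start: 190, duration: 10, V_T: 1.0, b_r: 24}
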