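# Severe OSA (AHI = 48): eight 15-s apneas in 10 min (2 min obstructed).
V_T: 0.5
V_D: 0.15
V_End: 2.3
b_r: 12
total_duration: 600
stabilization_time: 360
events:
  - {kind: apnea, start: 40,  duration: 15}
  - {kind: apnea, start: 110, duration: 15}
  - {kind: apnea, start: 180, duration: 15}
  - {kind: apnea, start: 250, duration: 15}
  - {kind: apnea, start: 320, duration: 15}
  - {kind: apnea, start: 390, duration: 15}
  - {kind: apnea, start: 460, duration: 15}
  - {kind: apnea, start: 530, duration: 15}
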