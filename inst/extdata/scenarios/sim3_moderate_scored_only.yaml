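# Moderate OSA (AHI = 24): four 20-s apneas in 10 min, no unscored events.
V_T: 0.5
V_D: 0.15
V_End: 2.3
b_r: 12
total_duration: 600
stabilization_time: 360
events:
  - {kind: apnea, start: 60,  duration: 20}
  - {kind: apnea, start: 195, duration: 20}
  - {kind: apnea, start: 330, duration: 20}
  - {kind: apnea, start: 465, duration: 20}
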