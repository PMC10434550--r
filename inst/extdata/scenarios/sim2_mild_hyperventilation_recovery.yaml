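# Mild OSA (AHI = 12): each 20-s apnea followed by 20 s of
# hyperventilation (b_r = 24/min) before normal breathing resumes.
V_T: 0.5
V_D: 0.15
V_End: 2.3
b_r: 12
total_duration: 600
stabilization_time: 360
events:
  - {kind: apnea, start: 60,  duration: 20}
  - {kind: hyperventilation, start: 80,  duration: 20, b_r: 24}
  - {kind: apnea, start: 360, duration: 20}
  - {kind: hyperventilation, start: 380, duration: 20, b_r: 24}
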