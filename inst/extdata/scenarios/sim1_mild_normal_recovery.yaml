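# Mild OSA (AHI = 12): two 20-s apneas in 10 min, normal-breathing recovery.
V_T: 0.5
V_D: 0.15
V_End: 2.3
b_r: 12
total_duration: 600
stabilization_time: 360
events:
  - {kind: apnea, start: 60,  duration: 20}
  - {kind: apnea, start: 360, duration: 20}
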