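# Normal subject validation pattern: quiet sinusoidal breathing.
V_T: 0.5
V_D: 0.15
V_End: 2.3
b_r: 12
total_duration: 120
stabilization_time: 360
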