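# Four 25-s hypopneas with 50% airflow reduction (AHI = 0 when the 4%
# desaturation criterion is not met).
V_T: 0.5
V_D: 0.15
V_End: 2.3
b_r: 12
total_duration: 600
stabilization_time: 360
events:
  - {kind: hypopnea, start: 60,  duration: 25, airflow_fraction: 0.5}
  - {kind: hypopnea, start: 195, duration: 25, airflow_fraction: 0.5}
  - {kind: hypopnea, start: 330, duration: 25, airflow_fraction: 0.5}
  - {kind: hypopnea, start: 465, duration: 25, airflow_fraction: 0.5}
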