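# Reference platform scenario: 6-month disease control endpoint
endpoint: DCR
theta_t: 0.72
delta: 0.05
control_cap: 30
comparison: final
priors:
  experimental: [1.0, 1.0]
  control: [1.0, 1.0]
accrual:
  kind: poisson
  rate: 5.0
reps: 1000
seed: 1
arms:
- arm_id: control
  role: control
  true_rate: 0.7
  open_time: 0
- arm_id: arm1
  role: experimental
  true_rate: 0.7
  planned_n: 30
  open_time: 0
- arm_id: arm2
  role: experimental
  true_rate: 0.8
  planned_n: 30
  open_time: 6
- arm_id: arm3
  role: experimental
  true_rate: 0.9
  planned_n: 30
  open_time: 12
- arm_id: arm4
  role: experimental
  true_rate: 0.95
  planned_n: 30
  open_time: 18
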