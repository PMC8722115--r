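# Reference platform scenario: major pathological response endpoint
endpoint: MPR
theta_t: 0.67
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
  true_rate: 0.13
  open_time: 0
- arm_id: arm1
  role: experimental
  true_rate: 0.195
  planned_n: 30
  open_time: 0
- arm_id: arm2
  role: experimental
  true_rate: 0.26
  planned_n: 30
  open_time: 6
- arm_id: arm3
  role: experimental
  true_rate: 0.13
  planned_n: 30
  open_time: 12
- arm_id: arm4
  role: experimental
  true_rate: 0.3
  planned_n: 30
  open_time: 18
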