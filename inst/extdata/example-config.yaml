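# Example configuration: glassy model on a fast-relaxing substrate.
# Any key may be omitted; the shipped defaults then apply.
clutches:
  n_clutches: 45
  k_c: 0.8
  r_on: 1
  f_bond: 1.8
motors:
  n_motors: 50
  f_motor: 2
  v_u: 120
substrate:
  tau_s: 10          # seconds; eta is derived as tau_s * k_a
glassy:
  beta: 1.5
  tau_min: 1
  off_time_mode: glassy
run:
  duration: 2000
  record_interval: 10
  n_cells: 50
  seed: 1
sweep:
  beta: [1.5, 3, 10]
  tau_s: [0.1, 1, 10, 100, 1000]
  reps: 20
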