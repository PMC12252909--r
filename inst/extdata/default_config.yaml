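profile: default
params: []
'N': 1000
kernel:
  family: single_exp
  alpha: 2.0
activity:
  type: fraction
  f: 0.99
respond:
  freq_hz: 2000.0
  amplitude: 1.0
selftune:
  h0_multiple: 10.0
  noise_sd: 1.0
  n_steps: 600.0
phase_diagram:
  alpha:
  - 0.5
  - 1.0
  - 2.0
  - 4.0
  - 8.0
  f:
  - 0.9
  - 0.99
  - 1.0
analyses: modes
seed: 1
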