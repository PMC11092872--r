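mode: minimal
dims:
- 8
- 8
- 8
params:
  v_p: -0.5
  n_max: 40
  mu_b: -1.0
  j_bulk: 0.5
  j_int: 1.0
schedule:
  sweeps: 2000
  equil: 500
  meas_every: 10
seed: 1
out_dir: minimal-example-out
n_reservoir: 0
collect_frames: no
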