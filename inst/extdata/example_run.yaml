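# Example cardiotwin pipeline configuration.
#   cardiotwin pipeline --config example_run.yaml -o out/
# Unset fields fall back to the constructor defaults and are recorded in
# the run manifest.
stages: [mesh, fibers, ep, ecg]
seed: 7
anatomy:
  lv_radii: [28, 28, 48]
  lv_wall_thickness: 10
  rv_wall_thickness: 3
  edge_length: 12
ep:
  tau_close: 160
  c_myo: 413
  c_lv: 1600
  c_rv: 2200
ep_duration: 480
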