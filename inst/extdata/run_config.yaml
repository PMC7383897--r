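donor: I
n_events: 10000.0
seed: 1.0
geometry:
  width: 170.0
  height: 30.0
  loops: 6.0
  curvature_radius: .na
  n_outlets: 4.0
fluid:
  density: 1000.0
  viscosity: 0.001
candidate_flow_rates:
- 0.2
- 0.4
- 0.6
- 0.8
- 1.0
focusing_model: ~
filter:
  pore_size: 3.0
  passage:
    enucleated: 0.4
    nucleated: 0.004
    nucleus: 0.004
    debris: 0.5
batch:
  volume: 10.0
  dead_volume: 1.5
  minutes: 10.0
  sedimentation_loss: 0.05
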