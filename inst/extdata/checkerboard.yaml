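name: checkerboard
n_states: 3
lattice_shape:
- 32
- 32
offsets:
- - 0
  - 1
- - 1
  - 0
potentials:
- - - 0.0
    - 0.0
    - -1.0
  - - 0.0
    - 0.0
    - 0.0
  - - -1.0
    - 0.0
    - 0.0
- - - 0.0
    - 0.0
    - -1.0
  - - 0.0
    - 0.0
    - 0.0
  - - -1.0
    - 0.0
    - 0.0
beta_grid:
- 0.0
- 0.05
- 0.1
- 0.15
- 0.2
- 0.3
- 0.4
- 0.6
- 0.8
- 1.0
ground_state_tile:
- - 0
  - 2
- - 2
  - 0
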