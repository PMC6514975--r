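# Single posterior-retina focus with the 5 MHz / 512-element racing array.
array: type_i
medium:
  sound_speed: 1500
  density: 1000
solver:
  method: weighted
  truncation_tol: 1.0e-8
  max_iters: 20
target:
  foci:
    - [0, 0, -12]
  amplitude: 1
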