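dims: 1
ligand_mass: 50.0
orthosteric_center: 4.5
confinement:
  box_halflength: 4.25
  wall_k: 20.0
  center: 6.75
wells:
- center: 4.5
  depth: 6.0
  width: 0.8
  radius: 0.0
- center: 9.0
  depth: 6.0
  width: 0.8
  radius: 0.0
barriers: []
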