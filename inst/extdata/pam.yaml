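dims: 3
ligand_mass: 200.0
orthosteric_center:
- 0.0
- 0.0
- 0.0
confinement:
  box_halflength: 25.0
  wall_k: 10.0
  center:
  - 0.0
  - 0.0
  - 0.0
wells:
- center:
  - 0.0
  - 0.0
  - 0.0
  depth: 3.0
  width: 3.0
  radius: 0.0
- center:
  - 0.0
  - 0.0
  - 0.0
  depth: 7.0
  width: 2.5
  radius: 15.0
barriers:
- center:
  - 0.0
  - 0.0
  - 0.0
  height: 3.0
  width: 2.0
  radius: 10.0
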