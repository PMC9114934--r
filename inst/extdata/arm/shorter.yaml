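name: shorter
lengths:
- 0.31
- 0.22
- 0.1
masses:
- 0.02
- 0.012
- 0.005
inertias:
- - 0.0001602
  - 0.0001602
  - 9.0e-06
- - 3.75e-06
  - 4.84e-05
  - 4.84e-05
- - 2.25e-06
  - 4.1666667e-06
  - 4.1666667e-06
lower:
- -1.57
- -0.85
- -0.85
- -1.5
- -1.5
- -0.5
- -1.05
upper:
- 0.7
- 1.57
- 0.85
- 1.05
- 1.57
- 0.5
- 1.05
gravity:
- 0.0
- 0.0
- -9.81
torque_limit: 20.0
joint_damping:
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
- 0.01
shoulder_tilt: -0.35
integrator_substep: 0.002
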