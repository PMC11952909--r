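# Example spinepinn pipeline configuration.
# Any omitted key falls back to the package default; unknown keys are
# rejected. Units are carried in the key names (mm, GPa, MPa).
seed: 1
phantom:
  n_vertebrae: 5
  vertebra_height_mm: 28
  disc_height_mm: 10
  cross_section: cylinder
  radius_mm: 20
  mesh_resolution_mm: 7
dataset:
  n_materials: 29
  n_materials_calibration: 48
  E_bone_GPa: [10, 25]
  E_disc_MPa: [1, 4.1]
  nu_bone: [0.1, 0.4]
  nu_disc: [0.45, 0.48]
net:
  hidden: [64, 32, 16]
  lambda1: 0.1
  lambda2: 0.1
loop:
  max_iter: 10
  tol: 0.001
  load_magnitude_mm: 1.4
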