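# demo configuration for the polysticker CLI
# polysticker build --config demo.yaml --out-dir demo_out
# polysticker run   --config demo.yaml --data demo_out/system.data --out-dir demo_out
chains:
  - pattern: [A, spacer, spacer, spacer, spacer]
    repeats: 10
    count: 20
  - pattern: [B, spacer, spacer, spacer, spacer]
    repeats: 10
    count: 20
box: [200, 200, 200]
complementary:
  - [A, B]
min_separation: 10
seed: 1
T: 310
forcefield:
  Es_kT: 6
  Ens_kT: 0.3
simulation:
  dt: 30
  t_damp: 2000
  n_steps: 100000
  thermo_every: 10000
  bond_attempt_every: 20
  seed_thermostat: 3
  seed_bonds: 4
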