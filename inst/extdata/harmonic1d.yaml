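# Minimal PI-FEP run: one particle in a 1-D harmonic well (reduced units),
# alchemical doubling of the mass.
model:
  kind: harmonic-1d
  parameters:
    k: 1.0
    r0: 0.0
  masses: [1.0]
temperature: 0.333333333
reduced: true
sampler:
  name: metropolis
  n_steps: 20000
  step_size: 1.5
  save_interval: 100
  n_equilibration: 1000
estimator:
  P: 32
  n_paths: 200
  n_discard: 10
  n_blocks: 10
isotopes:
  atom_indices: [1]
  masses_light: [1.0]
  masses_heavy: [2.0]
seed: 1
output_prefix: harmonic1d
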