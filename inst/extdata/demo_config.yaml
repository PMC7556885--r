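# Demo pipeline: synthetic susceptibility spectra with a known
# sub-diffusion exponent, a heavy-tailed CTRW trajectory ensemble, and an
# RJ simulation driven by the extracted residence-time distribution.
seed: 42
temperature: 280
q_range: [0.7, 1.5]
msd_window: [5, 1000]
hydration_levels: [2.0, 4.0]
spectra:
  beta_star: 0.8
  q_values: [0.7, 0.9, 1.1, 1.3, 1.5]
  tau0: 10
  noise_level: 0.02
trajectories:
  model: {kind: pareto, tail_exponent: 0.7, t_min: 1.0}
  step_length: 3.5
  n_particles: 400
  t_max: 2000
rj:
  step_length: 3.5
  n_particles: 400
  t_max: 2000
outdir: hydrosub_out
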