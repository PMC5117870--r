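# Attractive discrete ensemble and its bearing-to-source histogram:
# the orbital signature with modes near +-90 degrees.
model: discrete
agent:
  theta_b: 10        # baseline turn, degrees
  g: -5              # attractive gain, radians per concentration unit
  noise_sigma: 10    # heading noise, degrees/step
  n_steps: 800
field:
  type: gaussian
  mu_x: 50
  mu_y: 50
  sigma_x: 10
  sigma_y: 10
  rho: 0
  c: 5000
  xlim: [0, 100]
  ylim: [0, 100]
ensemble:
  n_agents: 30
  seed: 1
analyses:
  - bearings
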