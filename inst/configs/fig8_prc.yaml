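# Phase-response curve of the continuous-time oscillator: net bearing
# change of a bilateral sensory step across 102 onset phases per cycle.
model: cpg
agent:
  b_t: 19
ensemble:
  n_agents: 1
  seed: 1
analyses:
  - kind: prc
    n_points: 102
    amplitudes: [-2, 2]
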