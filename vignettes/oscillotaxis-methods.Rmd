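---
title: "Oscillatory taxis: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillatory taxis: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The hypothesis the package embodies

Drosophila larvae crawl up (or down) odour, light and temperature gradients.
A common way to describe this behaviour is as a repertoire of discrete
actions — runs, stops, head casts, turns — with sensory input biasing the
transitions between them. This package implements the alternative
hypothesis: the anterior body oscillates laterally all the time, and taxis
emerges when the perceived change of stimulus intensity continuously
modulates the *amplitude* of that oscillation, while its left/right
*direction* is fixed by the oscillator's own phase. Nothing selects
actions; orientation is a closed loop between an oscillator, a body, and
an odour landscape.

Two agents embody this at different levels of abstraction, sharing the
same odour environments and the same trajectory statistics.

## The discrete-time agent

A point with position $(x_n, y_n)$ and heading $\theta_n$ updates once per
step, in this strict order:

$$\theta_n \leftarrow \theta_{n-1} + H\!\big(\theta_B + g\,(s_T + p_{n-1})\big)\,(-1)^n \;[+\,Z_n]$$
$$x_n \leftarrow x_{n-1} + \lambda \sin\theta_n,\qquad
  y_n \leftarrow y_{n-1} + \lambda \cos\theta_n$$
$$s_n \leftarrow C(x_n, y_n),\qquad p_n \leftarrow s_n - s_{n-1}$$

with $s_0 = 0$. $H$ clips the commanded amplitude to $[0, \pi]$: a turn can
shrink to going straight but cannot flip sides, and cannot exceed a U-turn.
The $(-1)^n$ factor is the oscillation — left on odd steps, right on even.
With a negative gain $g$, rising concentration straightens the path and
falling concentration enlarges the next turn: attraction. Positive $g$
gives aversion; $g = 0$, neither.

Parameters and their defaults (`discrete_config()`):

* `theta_b` = 10° — baseline oscillation amplitude, the small spontaneous
  zig-zag. Taxis is robust to this choice.
* `g` — the single sensorimotor degree of freedom, in radians of turn per
  concentration unit; its sign sets valence and its magnitude the strength
  of the response. −5 is the reference attractive value.
* `s_t` = 0 — optional tonic term; every shipped analysis is driven by the
  phasic term only.
* `lambda_step` = 1 mm; one step is taken to last one second, so the
  nominal crawl speed is 1 mm/s and "3 minutes" means 180 steps. The step
  duration is a convention of this package, not a measured quantity.
* `noise_sigma` — i.i.d. Gaussian heading noise in degrees, added *outside*
  the hard limit, so strong noise can flip the effective turn direction.
  10° is the reference noisy condition.

If a step would leave the arena, the heading is re-drawn uniformly among
orientations whose next step stays inside (the position does not change).
The trajectory records the applied turn (post-limit, pre-noise) per step,
but the turn-event statistics score the *realized* per-step heading change
(noise included, boundary resets excluded): with noise off the two
coincide, and with noise on the realized change is what an observer of the
track would measure — it is also the only definition under which the
no-signal control can produce above-threshold events at all.

## The continuous-time agent

Here the oscillation is produced by a two-compartment half-center CPG
(adapted from lamprey locomotion models). Each side has an excitatory pool
$E$ and a cross-inhibitory interneuron $C$; all rates pass through the
Naka-Rushton function $R(x, h) = m\,x^2 / (h^2 + x^2)$ for $x \ge 0$ (else
0), with $m = 100$ spikes/s. Spike-rate adaptation raises each neuron's
half-threshold $h = 64 + g(A)\,H$ through a slow variable $H$, and the
sensory drive $A$ neuromodulates the adaptation itself:
$g(A) = 6 + (0.09A)^2$, $\tau_H(A) = 35 / (1 + 0.04A^2)$.

The eight neural equations are implemented exactly as printed in the
reference formulation, including its asymmetry: *both* adaptation
variables of a compartment relax toward that compartment's $E$ rate. A
switch (`adapt_tracks_own`) exposes the plausible intended variant in
which each $C$ neuron's adaptation tracks its own rate; the as-printed
form is the default because fidelity beats conjecture, and with the
reference parameters both forms oscillate.

The rate difference $E_L - E_R$ drives a non-dimensionalized
spring-mass-damper, $\ddot\theta = -2\zeta\dot\theta - k\theta +
(E_L - E_R)$ with $\zeta = 1/2$, $k = 1$, standing for the viscoelastic
restoration of the bending body. The bearing and position integrate as
$\dot B = \theta / 10$, $\dot x = \sin B / 10$, $\dot y = \cos B / 10$.

**Units of the heading plant.** The plant is non-dimensionalized, and the
parameter set makes its output oscillate with half peak-to-peak almost
exactly 10 raw units at 0.28 Hz — the published "±10 degrees at around
0.3 Hz". We therefore read $\theta$ in degrees. The bearing, by contrast,
feeds $\sin B$ and $\cos B$ directly, so it integrates in radians: one
half-sweep of the ±10 oscillation advances $B$ by about 1.1 rad, a clearly
visible zig-zag of the path, commensurate with larval head casts. Reading
$B$ in degrees instead would yield ±2° wiggles — a nearly straight line,
under which the sensory closed loop cannot steer at all. All reporting
surfaces convert angles to degrees.

The sensory unit fires at $A = b_T + G\,\mathrm{d}C/\mathrm{d}t$ with
$b_T = 19$; the concentration derivative is computed analytically (field
gradient dotted with velocity), not by differencing the sensed series, so
it is independent of the integrator's step size. $A$ is floored at zero —
a firing rate cannot be negative; the floor is a package decision exposed
as `floor_A` since the reference formulation does not state one.

The 13 coupled ODEs are integrated with `deSolve`'s `lsoda`
(adaptive, stiff-capable) at `rtol = 1e-8`, `atol = 1e-10`; halving the
tolerances moves the measured oscillation frequency by well under 0.1%.
Output is sampled at 0.1 s.

## Step perturbations and the phase-response curve

`step_response_bearing_change()` applies a bilateral step of amplitude
$A_m$ to the sensory unit at time $t_s$ and returns the net bearing change
it causes. After a perturbation the oscillator relaxes to a (possibly
frequency-shifted) limit cycle whose mean heading is zero, so the bearing
converges to a constant plus a bounded oscillation; we therefore average
the bearing over whole cycles (delimited by $E_L$ burst peaks) in the
perturbed and unperturbed runs separately and take the difference, once
successive per-cycle means drift by less than 0.05° (default horizon 60 s
after onset). `phase_response_curve()` sweeps $t_s$ across one cycle —
phase 0 at an $E_L$ peak — for a grid of amplitudes.

Two caveats, both discoverable with the package: steps more negative than
about −2 spikes/s push the reference oscillator onto a slow *asymmetric*
cycle whose mean heading is nonzero — the bearing then drifts indefinitely
and the net change is ill-defined (the function warns). The reference
amplitude grid is therefore ±2; the published figure's amplitudes are not
printed, so the grid is this package's choice.

## Odour environments and their scales

Fields are either analytic scaled bivariate Gaussians (`gaussian_field()`)
or rectangular grids with bilinear interpolation (`grid_field()`, CSV
matrix + JSON sidecar). Queries outside a grid's hull or a Gaussian
field's arena limits return `NA` — a signal the agents translate into
their boundary rule; fields never clamp or extrapolate. `scale_field()`
models stronger sources by scaling all concentrations, and commutes
exactly with evaluation.

The recorded gradient maps behind the original experiments are not
available, and no physical concentration scale is published, so absolute
concentration units here are arbitrary. What can be fixed is the *regime*.
`reference_field()` freezes one choice per agent, made once:

* **Discrete arena** — isotropic Gaussian, σ = 10 mm, centred in a
  100 × 100 mm arena, amplitude $c = 5\times10^3$. At the reference gain
  $g = -5$ the strongest one-step signal near the source commands ≈140°
  turns: above both the 30° and 90° event thresholds the analyses score
  (so large-turn and U-turn statistics are populated), while an
  unsaturated orbital zone remains beyond ≈1.5σ. At the printed
  continuous-model amplitude $c = 10^3$ no turn could ever exceed ≈40°
  and the published large-turn analyses would be empty.
* **Continuous arena** — Gaussian with the continuous model's shape
  (σ = 10, ρ = 1/5), amplitude $c = 2\times10^4$, unbounded. At the
  reference gain $G = 70$ the closed-loop drive perturbations reach
  several spikes/s — the amplitude scale at which step inputs measurably
  deflect the bearing — which puts $G = 70$ in the orbital and $G = 140$
  in the crossing-over regime. Only the product $G \cdot c$ matters
  (verified numerically), so this is a choice of units, not of dynamics.

## Trajectory statistics

* **Spectra** (`heading_speed_spectrum()`): raw DFT magnitude of the
  heading-velocity series at 0.1 s sampling, averaged across trajectories.
  No taper is applied; spectral leakage is as for a plain DFT, which
  matters only for closely spaced tones, not for locating the dominant
  rhythm.
* **Turn events** (`detect_turns()`): two printed exclusion rules are
  implemented verbatim — an above-threshold turn *not followed* by another
  (the rule for turn-rate/angle statistics, `is_large`) and one *not
  preceded* by another (the rule for first-turn bias, `is_first`). The two
  sets overlap but neither contains the other; on the sequence
  (40°, 35°, 5°) the first rule selects 35° and the second 40°. For the
  continuous agent a "turn" is the net heading change between successive
  zero crossings of heading velocity (one half-sweep), which makes the
  same angular thresholds applicable to both agents.
* **Bearing to source** (`bearing_to_source()`): signed angle between
  heading and the agent-to-source direction, wrapped to (−180°, 180°] with
  the half-turn tie at +180; positive means the odour lies to the agent's
  right (the sign convention is this package's; the published histograms
  are side-symmetric).
* **First-turn bias, preference index, event-aligned sensory history,
  turn statistics by bearing** follow their printed definitions; bootstrap
  95% confidence intervals use 1000 seeded resamples (the reference states
  "±95% CI" without a method).
* **Orbital persistence** (`orbital_persistence()`): the statistic behind
  the gain-doubling comparison — absolute net winding of the
  source-relative polar angle divided by total absolute winding. A clean
  orbit scores 1; crossing-over paths reverse their circulation at every
  pass and score toward 0. Doubling the continuous gain from 70 to 140 in
  the reference arena drops the ensemble median from 1.00 to ≈0.8.

## The synthetic track generator

`synthesize_track()` emulates the structure of multi-point tracker output
so the whole analysis suite is testable without the unpublished
recordings: a three-point (tail/centroid/head) larva whose centroid
advances with a peristaltic speed rhythm (default 1.0 Hz, the published
crawl rhythm) while the head axis oscillates laterally (default 0.3 Hz,
the published anterior-body rhythm; default sweep amplitude 30°), with an
optional schedule of peristalsis-inhibition stops and a slow path
curvature. Frame rate defaults to 7 fps and duration to 60 s, matching
the published recording protocol. `derive_channels()` recovers the
generator's frequencies to within one spectral bin and its sweep
amplitude to within a few percent, which is exactly what the tests
assert.

What the generator does *not* emulate: posture-dependent coupling between
peristalsis and head sweeps, tracking noise structure (only i.i.d. jitter
is available), body-length changes, and any sensory coupling. Passing
tests therefore certify the analysis code's arithmetic and conventions on
kinematically consistent input — not that real tracker data are this
clean.

## Degenerate inputs and tie-breaks

Bearings at the exact source position are undefined and dropped. Bearing
histograms use half-open bins on (−180°, 180°] with the +180 tie. Empty
histogram subsets are flagged, and empty bearing bins in turn-rate tables
are `NA`, not zero. Tracks with coincident body points get those samples
flagged invalid; single-frame coordinate gaps are linearly interpolated
(and reported), longer gaps are format errors. A boundary reset with no
feasible orientation (an arena narrower than a step in both axes) is a
simulation error.

## Problem sizes

The shipped tests and the reproduction script run the unstimulated
continuous agent for 200 s (50 s transient discarded), discrete ensembles
of 30–60 agents × 800 steps, phase-response grids of 9 points × 2
amplitudes, and 8 continuous taxis runs of 400 s per gain; these sizes
give stable statistics for every claim they support while keeping a full
check of the package in the minutes range. The bundled
`inst/configs/fig8_prc.yaml` requests the full 102-point curve.

## Known limitations

* Peristalsis and stopping are outside both agents by design; the
  synthetic track generator, not the agents, carries the stop/crawl
  structure.
* The discrete agent's closed loop is chaotic near a strong source:
  trajectories are reproducible under a seed but shadow symmetry
  arguments only over finite horizons.
* Deeply inhibitory steps (A well below its tonic rate) leave the
  continuous oscillator in an asymmetric regime where a net bearing
  change cannot be defined.
* Concentration units are arbitrary throughout; only regime-level
  statements (orbital vs crossing-over, saturated vs graded turns) are
  meaningful across field scales.
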