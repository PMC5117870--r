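Package: oscillotaxis
Title: Oscillatory Agent Models and Trajectory Statistics for Larval Taxis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates gradient-following (taxis) behaviour of Drosophila
    larvae under the hypothesis that steering emerges from direct sensory
    modulation of a continuous lateral oscillation of the anterior body.
    Provides a discrete-time point agent whose alternating left/right
    re-orientations are linearly modulated by the one-step change in sensed
    odour concentration, and a continuous-time agent in which a two-compartment
    Naka-Rushton half-center oscillator with spike-rate adaptation drives a
    spring-mass-damper heading plant. Includes analytic Gaussian and gridded
    odour fields, phase-response-curve analysis of the neural oscillator,
    trajectory statistics (heading-velocity spectra, turn detection, bearing
    distributions, first-turn bias, preference index, event-aligned sensory
    history), and readers, writers and a synthetic generator for multi-point
    larval track recordings with derived body-bend, angular-velocity and
    tail-speed channels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
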