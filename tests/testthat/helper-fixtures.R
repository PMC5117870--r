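# Shared, lazily built simulation fixtures. Everything is generated in code
# under fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# 200 s of the unstimulated CPG agent at the reference parameter set
cpg_baseline_run <- function() fixture("cpg_baseline", function() {
  simulate_cpg(cpg_params(), NULL, duration = 200, dt = 0.1)
})

# reference attractive discrete ensemble (the orbital condition)
discrete_ensemble <- function(g = -5, factor = 1, seed = 1, n = 30) {
  key <- sprintf("disc_%g_%g_%d_%d", g, factor, seed, n)
  fixture(key, function() {
    cfg <- discrete_config(theta_b = 10, g = g, noise_sigma = 10,
                           n_steps = 800, seed = seed)
    simulate_discrete_ensemble(cfg, reference_field("discrete", factor = factor),
                               n_agents = n)
  })
}

discrete_source <- c(50, 50)

# a small synthetic larval track with known rhythms
synthetic_track_fixture <- function() fixture("syn_track", function() {
  synthesize_track(fps = 7, duration = 120, peristalsis_hz = 1.0,
                   lateral_hz = 0.3, sweep_amplitude_deg = 30, seed = 42)
})

# build a continuous-style trajectory from an explicit heading-velocity series
traj_from_velocity <- function(v, dt = 0.1) {
  taxis_trajectory(data.frame(t = seq_along(v) * dt - dt, theta_dot = v,
                              theta = cumsum(v) * dt,
                              x = 0, y = 0, B = 0),
                   model = "cpg")
}

# build a discrete-style trajectory from an explicit per-step turn series (deg)
traj_from_turns <- function(turns_deg, theta0 = 0, s = NULL, p = NULL) {
  th <- deg2rad(cumsum(c(theta0, turns_deg)))
  n <- length(th)
  taxis_trajectory(data.frame(t = 0:(n - 1),
                              x = cumsum(c(0, sin(th[-1]))),
                              y = cumsum(c(0, cos(th[-1]))),
                              theta = th,
                              s = s %||% rep(0, n), p = p %||% rep(0, n),
                              turn = deg2rad(c(0, turns_deg)),
                              reset = rep(FALSE, n)),
                   model = "discrete")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

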