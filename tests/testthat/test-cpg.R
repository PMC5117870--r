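test_that("Naka-Rushton response has the printed shape", {
  expect_identical(naka_rushton(-1, 64), 0)
  expect_equal(naka_rushton(64, 64), 50, tolerance = 1e-12)
  expect_equal(naka_rushton(1e7, 64), 100, tolerance = 1e-6)
  x <- seq(0.1, 300, by = 0.7)
  r <- naka_rushton(x, 64)
  expect_true(all(diff(r) > 0))          # strictly increasing on x > 0
  expect_true(all(r >= 0 & r <= 100))
  expect_error(naka_rushton(1, h = 0), "h must be")
})

test_that("neuromodulation follows the adaptation gain and time constant laws", {
  nm0 <- neuromodulation(0)
  expect_identical(nm0$g_adapt, 6)
  expect_identical(nm0$tau_h, 35)
  nm19 <- neuromodulation(19)
  expect_equal(nm19$g_adapt, 8.9241, tolerance = 1e-10)
  expect_equal(nm19$tau_h, 2.266839378238342, tolerance = 1e-12)
  # the A-dependent part of the gain scales quadratically
  expect_equal(neuromodulation(38)$g_adapt - 6, 4 * (nm19$g_adapt - 6),
               tolerance = 1e-12)
  expect_error(neuromodulation(-1), ">= 0")
})

test_that("neural derivatives match an independent evaluation at the reference state", {
  # independent oracle: a literal transcription of the eight rate equations,
  # written separately from the integrator's right-hand side
  oracle <- function(s, A) {
    R <- function(x, h) if (x < 0) 0 else 100 * x^2 / (h^2 + x^2)
    gA <- 6 + (0.09 * A)^2
    tH <- 35 / (1 + 0.04 * A^2)
    tau <- 0.1
    c(EL  = (-s["EL"] + R(A + 3 * s["EL"] - 4 * s["CR"], 64 + gA * s["HEL"])) / tau,
      HEL = (-s["HEL"] + s["EL"]) / tH,
      CL  = (-s["CL"] + R(A + 0.1 * s["EL"] - 4 * s["CR"], 64 + gA * s["HCL"])) / tau,
      HCL = (-s["HCL"] + s["EL"]) / tH,
      ER  = (-s["ER"] + R(A + 3 * s["ER"] - 4 * s["CL"], 64 + gA * s["HER"])) / tau,
      HER = (-s["HER"] + s["ER"]) / tH,
      CR  = (-s["CR"] + R(A + 0.1 * s["ER"] - 4 * s["CL"], 64 + gA * s["HCR"])) / tau,
      HCR = (-s["HCR"] + s["ER"]) / tH)
  }
  st <- cpg_initial_state()
  d <- cpg_derivatives(st, cpg_params(), A = 19)
  expect_equal(unname(d[1:8]), unname(oracle(st, 19)), tolerance = 1e-12)
  # a second, asymmetric state probes every term
  st2 <- st; st2[1:8] <- c(33, 12, 7, 4, 61, 9, 15, 2)
  d2 <- cpg_derivatives(st2, cpg_params(), A = 25)
  expect_equal(unname(d2[1:8]), unname(oracle(st2, 25)), tolerance = 1e-12)
})

test_that("the all-zero state with no drive is a neural fixed point", {
  st <- cpg_initial_state(); st[] <- 0
  d <- cpg_derivatives(st, cpg_params(), A = 0)
  expect_equal(unname(d[1:10]), rep(0, 10), tolerance = 1e-12)
  # the agent never stops: forward speed stays 1/10 along the bearing
  expect_equal(unname(d[c("x", "y")]), c(0, 0.1), tolerance = 1e-12)
})

test_that("left-right symmetric states stay symmetric", {
  st <- cpg_initial_state()
  st[c("EL", "HEL", "CL", "HCL")] <- c(40, 5, 10, 3)
  st[c("ER", "HER", "CR", "HCR")] <- c(40, 5, 10, 3)
  d <- cpg_derivatives(st, cpg_params(), A = 19)
  expect_identical(unname(d[1:4]), unname(d[5:8]))
  expect_identical(unname(d["theta_dot"]), 0)   # no net torque
})

test_that("exchanging left and right initial conditions mirrors the heading", {
  p <- cpg_params()
  a <- simulate_cpg(p, NULL, 40, init = cpg_initial_state(), dt = 0.1)
  sw <- cpg_initial_state()
  sw[c("EL", "HEL", "CL", "HCL", "ER", "HER", "CR", "HCR")] <-
    sw[c("ER", "HER", "CR", "HCR", "EL", "HEL", "CL", "HCL")]
  b <- simulate_cpg(p, NULL, 40, init = sw, dt = 0.1)
  expect_equal(a$theta, -b$theta, tolerance = 1e-5)
  expect_equal(a$EL, b$ER, tolerance = 1e-5)
})

test_that("rates stay within [0, m] and the E pools burst in antiphase", {
  tr <- cpg_baseline_run()
  expect_true(all(tr$EL >= 0 & tr$EL <= 100))
  expect_true(all(tr$ER >= 0 & tr$ER <= 100))
  expect_true(all(tr$CL >= 0 & tr$CL <= 100))
  post <- tr[tr$t >= 50, ]
  cc <- stats::ccf(post$EL, post$ER, lag.max = 40, plot = FALSE)
  expect_lt(cc$acf[cc$lag == 0], -0.5)                 # anticorrelated
  expect_equal(as.numeric(cc$lag[which.min(cc$acf)]), 0)  # most strongly at zero lag
})

test_that("the unstimulated heading rhythm sits at the reference frequency and amplitude", {
  s <- cpg_oscillation_summary(cpg_baseline_run(), transient = 50)
  expect_gt(s$frequency_hz, 0.25); expect_lt(s$frequency_hz, 0.35)
  expect_gt(s$amplitude_deg, 8.5); expect_lt(s$amplitude_deg, 11.5)
  # stiffness sanity: halving the integrator tolerances leaves the frequency
  tr2 <- simulate_cpg(cpg_params(), NULL, 200, dt = 0.1, rtol = 5e-9, atol = 5e-11)
  s2 <- cpg_oscillation_summary(tr2, transient = 50)
  expect_lt(abs(s2$frequency_hz - s$frequency_hz) / s$frequency_hz, 1e-3)
})

test_that("the heading plant matches its closed-form damped oscillation", {
  zeta <- 1/2; k <- 1
  rhs <- function(t, y, parms) {
    d <- heading_plant_derivatives(y[1], y[2], e_l = 0, e_r = 0, zeta = zeta, k = k)
    list(unname(d))
  }
  th0 <- 5
  out <- deSolve::ode(c(th0, 0), seq(0, 20, by = 0.05), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  wd <- sqrt(k - zeta^2)
  exact <- exp(-zeta * out[, 1]) *
    (th0 * cos(wd * out[, 1]) + (th0 * zeta / wd) * sin(wd * out[, 1]))
  expect_equal(unname(out[, 2]), exact, tolerance = 1e-8)
  # constant drive settles at (EL - ER) / k
  d <- heading_plant_derivatives(5, 0, e_l = 5, e_r = 0, zeta = zeta, k = k)
  expect_identical(unname(d), c(0, 0))
})

test_that("kinematics advance at constant speed along the bearing", {
  for (B in c(0, 0.7, -2.1)) {
    d <- kinematics_derivatives(theta = 3, B = B)
    expect_equal(unname(sqrt(d["dx"]^2 + d["dy"]^2)), 0.1, tolerance = 1e-12)
    expect_equal(unname(d["dB"]), 0.3, tolerance = 1e-12)
  }
  # constant heading bends the path at constant curvature: a circle
  tr <- cpg_baseline_run()
  sp <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / diff(tr$t)
  # sampled positions give chords, not arcs, hence the loose tolerance
  expect_equal(sp, rep(0.1, length(sp)), tolerance = 1e-3)
})

test_that("sensory drive follows the along-path concentration derivative", {
  p <- cpg_params(g_sens = 100)
  expect_identical(sensory_drive(NULL, 0, 0, 0.1, 0, p), 19)
  # flat field: tonic rate only
  flat <- grid_field(matrix(2, 4, 4), origin = c(-2, -2), cell_size = 1)
  expect_equal(sensory_drive(flat, 0, 0, 0.1, 0, p), 19, tolerance = 1e-12)
  # moving straight up a linear ramp of slope 1 at speed 0.1: A = b_t + G s v
  ramp <- grid_field(outer(0:8, rep(1, 9)) * 1, origin = c(-4, -4), cell_size = 1)
  expect_equal(sensory_drive(ramp, 0, 0, 0.1, 0, p), 19 + 100 * 1 * 0.1,
               tolerance = 1e-12)
  # moving down-gradient hard enough floors the rate at zero
  expect_identical(sensory_drive(ramp, 0, 0, -10, 0, p), 0)
  p2 <- cpg_params(g_sens = 100, floor_A = FALSE)
  expect_lt(sensory_drive(ramp, 0, 0, -10, 0, p2), 0)
})

test_that("continuous simulation is deterministic", {
  p <- cpg_params(g_sens = 70)
  f <- reference_field("cpg")
  a <- simulate_cpg(p, f, 30, init = cpg_initial_state(x = 5), dt = 0.1)
  b <- simulate_cpg(p, f, 30, init = cpg_initial_state(x = 5), dt = 0.1)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("step perturbations steer the bearing by sign and settle to zero drift", {
  p <- cpg_params()
  expect_identical(step_response_bearing_change(p, 0, 65), 0)
  prc <- fixture("prc_small", function()
    suppressWarnings(    # small residual per-cycle drift is expected here
      phase_response_curve(p, amplitudes = c(-2, 2), n_points = 9,
                           transient = 60, settle = 60)))
  vp <- prc$delta_b_deg[prc$a_m == 2]
  vn <- prc$delta_b_deg[prc$a_m == -2]
  # opposite steps steer to opposite sides (approximate sign flip)
  expect_gt(stats::cor(vp, -vn), 0.6)
  # the curve is smooth at this resolution and periodic over one cycle
  expect_lt(max(abs(diff(vp))), 0.5 * diff(range(vp)) + 1e-9)
  expect_lt(abs(vp[1] - vp[9]), 0.25 * diff(range(vp)))
  # and the response is not degenerate: phase changes the outcome
  expect_gt(diff(range(vp)), 0.1)
})
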