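test_that("heading-velocity spectra localise injected tones", {
  dt <- 0.1; n <- 2000
  t <- (0:(n - 1)) * dt
  pure <- traj_from_velocity(sin(2 * pi * 0.3 * t), dt)
  sp <- heading_speed_spectrum(list(pure), dt = dt)
  expect_equal(spectrum_peak(sp), 0.3, tolerance = 1 / (n * dt) + 1e-9)

  flat <- traj_from_velocity(rep(3, n), dt)
  sp0 <- heading_speed_spectrum(list(flat), dt = dt, demean = FALSE)
  expect_equal(sp0$frequency[which.max(sp0$mean_amplitude)], 0)
  expect_lt(max(sp0$mean_amplitude[-1]), 1e-10)

  two <- traj_from_velocity(2 * sin(2 * pi * 0.3 * t) + 1 * sin(2 * pi * 1.0 * t), dt)
  sp2 <- heading_speed_spectrum(list(two), dt = dt)
  a03 <- sp2$mean_amplitude[which.min(abs(sp2$frequency - 0.3))]
  a10 <- sp2$mean_amplitude[which.min(abs(sp2$frequency - 1.0))]
  expect_equal(a03 / a10, 2, tolerance = 0.05)   # injected ratio, leakage aside

  # non-uniform sampling is refused
  bad <- pure; bad$t[5] <- bad$t[5] + 0.03
  expect_error(heading_speed_spectrum(list(bad), dt = dt), "uniform")
  # averaging across trajectories is order-invariant
  spA <- heading_speed_spectrum(list(pure, two), dt = dt)
  spB <- heading_speed_spectrum(list(two, pure), dt = dt)
  expect_identical(spA$mean_amplitude, spB$mean_amplitude)
})

test_that("turn detection reproduces the two printed exclusion rules", {
  ev <- detect_turns(traj_from_turns(c(40, 35, 5)))
  expect_equal(ev$magnitude_deg, c(40, 35))
  expect_identical(ev$is_large, c(FALSE, TRUE))   # 40 is followed by a large turn
  expect_identical(ev$is_first, c(TRUE, FALSE))   # 35 is preceded by one

  expect_identical(nrow(detect_turns(traj_from_turns(rep(10, 6)))), 0L)

  ev95 <- detect_turns(traj_from_turns(c(5, 95, 5)))
  expect_identical(nrow(ev95), 1L)
  expect_true(ev95$is_large && ev95$is_first && ev95$is_huge)
})

test_that("turn rules agree with a brute-force oracle on all 3-step sequences", {
  # independent restatement of the two rules, applied position by position
  oracle <- function(m) {
    big <- m > 30
    list(large = which(big & !c(big[-1], FALSE)),
         first = which(big & !c(FALSE, big[-length(big)])))
  }
  vals <- c(5, 35, 40, 95)
  grid <- expand.grid(a = vals, b = vals, c = vals)
  for (i in seq_len(nrow(grid))) {
    m <- as.numeric(grid[i, ])
    ev <- detect_turns(traj_from_turns(m))
    o <- oracle(m)
    expect_identical(ev$index[ev$is_large] - 1L, as.integer(o$large))
    expect_identical(ev$index[ev$is_first] - 1L, as.integer(o$first))
  }
})

test_that("bearing to source uses the stated sign and wrap conventions", {
  north <- traj_from_turns(numeric(0), theta0 = 0)   # heading +y at origin
  expect_equal(bearing_to_source(north, c(0, 10)), 0)
  expect_equal(bearing_to_source(north, c(10, 0)), 90)    # odour right
  expect_equal(bearing_to_source(north, c(-10, 0)), -90)  # odour left
  expect_equal(bearing_to_source(north, c(0, -10)), 180)  # tie wraps to +180
  expect_true(is.na(bearing_to_source(north, c(0, 0))))   # at the source
})

test_that("bearing histograms normalise and reflect orbital geometry", {
  # an agent on a perfect anticlockwise circle keeps the source 90 deg right
  ang <- seq(0, 2 * pi, length.out = 401)[-401]
  circ <- taxis_trajectory(
    data.frame(t = seq_along(ang) - 1, x = 10 * cos(ang), y = 10 * sin(ang),
               theta = -ang,              # compass heading of the tangent
               s = 0, p = 0, turn = 0, reset = FALSE),
    model = "discrete")
  b <- bearing_to_source(circ, c(0, 0))
  expect_true(all(abs(abs(b) - 90) < 1.5))
  dist <- bearing_distribution(list(circ), c(0, 0), bins = 36)
  expect_equal(sum(dist$density), 1, tolerance = 1e-12)
  expect_true(all(abs(dist$mid[dist$count > 0]) %in% c(85, 95)))

  empty <- bearing_distribution(list(circ), c(0, 0), bins = 36,
                                min_distance = 100)
  expect_true(attr(empty, "empty"))
})

test_that("far-from-source random walks give a flat bearing distribution", {
  f <- gaussian_field(1e4, 1e4, 10, 10, c = 0,
                      xlim = c(-1e5, 1e5), ylim = c(-1e5, 1e5))
  cfg <- discrete_config(theta_b = 10, g = 0, noise_sigma = 20,
                         n_steps = 2000, seed = 8)
  th0 <- c(-150, -80, -10, 40, 110, 170)
  seeds <- split_seeds(8, 6)
  trs <- lapply(1:6, function(i) {
    ci <- cfg; ci$seed <- seeds[i]
    simulate_discrete(ci, f, 0, 0, th0[i])
  })
  dist <- bearing_distribution(trs, c(1e4, 1e4), bins = 12)
  expect_lt(max(abs(dist$density - 1 / 12)), 0.05)
})

test_that("first turns are unbiased without signal and follow signal strength", {
  src <- discrete_source
  null <- first_turn_bias(discrete_ensemble(g = 0, seed = 3, n = 60), src)
  expect_gt(null$n_events, 500)
  expect_lt(abs(null$p_correct - 0.5), 0.05)
  expect_equal(null$p_correct + null$p_wrong, 1, tolerance = 1e-12)

  low  <- first_turn_bias(discrete_ensemble(g = -2, factor = 0.5, seed = 3, n = 60), src)
  high <- first_turn_bias(discrete_ensemble(g = -2, factor = 1,   seed = 3, n = 60), src)
  gain <- first_turn_bias(discrete_ensemble(g = -5, factor = 0.5, seed = 3, n = 60), src)
  expect_lt(null$p_correct, low$p_correct)
  expect_lt(low$p_correct, high$p_correct)
  expect_lt(high$p_correct, gain$p_correct)

  # with the odour dead ahead neither side is favoured (null ensemble)
  bb <- null$by_bearing
  centre <- bb$mean_direction[abs(bb$mid) <= 15]
  expect_true(all(abs(centre) < 0.25))
})

test_that("preference index follows its definition and symmetries", {
  mk <- function(xs) lapply(xs, function(x)
    taxis_trajectory(data.frame(t = 0:1, x = c(50, x), y = c(50, 50),
                                theta = 0, s = 0, p = 0, turn = 0, reset = FALSE),
                     model = "discrete"))
  src <- c(25, 50)   # odour side: x < 50
  expect_identical(preference_index(mk(rep(10, 30)), src, midline = 50), 1)
  expect_identical(preference_index(mk(c(rep(10, 15), rep(90, 15))), src, midline = 50), 0)
  expect_equal(preference_index(mk(c(rep(10, 20), rep(90, 10))), src, midline = 50), 1/3)
  # an agent exactly on the midline counts to neither side but stays in N
  expect_equal(preference_index(mk(c(10, 90, 50)), src, midline = 50), 0)
  # antisymmetry under reflecting all positions about the midline
  xs <- c(10, 20, 60, 95, 40)
  expect_identical(preference_index(mk(xs), src, midline = 50),
                   -preference_index(mk(100 - xs), src, midline = 50))
})

test_that("event-aligned sensory history shows the pre-turn concentration drop", {
  src <- discrete_source
  trs <- discrete_ensemble(g = -5)
  evs <- lapply(trs, function(tr) {
    ev <- detect_turns(tr, source = src)
    ev[ev$is_huge, , drop = FALSE]
  })
  h <- sensory_history_around_events(trs, evs, window = 10, n_boot = 200)
  expect_gt(h$n_events, 200)
  at <- function(x, l) x[h$lag == l]
  # concentration drops into the turn: the sample right before the event
  # sits well below the earlier pre-event level ...
  expect_lt(at(h$s_mean, -1), at(h$s_mean, -5) - 0.1)
  # ... because the turn is driven by a strongly negative transient
  expect_lt(at(h$p_mean, -1), -0.2)
  expect_lt(at(h$p_mean, -1), min(at(h$p_mean, -5), at(h$p_mean, 5)) - 0.1)
  # confidence intervals bracket the means
  expect_true(all(h$s_lo <= h$s_mean & h$s_mean <= h$s_hi))

  # shuffling the event times removes the pre-event structure
  set.seed(1)
  sh <- lapply(seq_along(trs), function(k) {
    ev <- evs[[k]]
    if (nrow(ev) > 0) ev$index <- sample(15:786, nrow(ev))
    ev
  })
  h0 <- sensory_history_around_events(trs, sh, window = 10, n_boot = 200)
  at0 <- function(x, l) x[h0$lag == l]
  expect_lt(abs(at0(h0$s_mean, -1) - at0(h0$s_mean, -5)), 0.1)
  expect_lt(abs(at0(h0$p_mean, -1)), 0.1)
})

test_that("down-gradient motion yields negative pre-event transients", {
  # an agent walked straight down a linear ramp senses p < 0 at every step
  ramp <- grid_field(outer(seq(100, 2, length.out = 50), rep(1, 5)),
                     origin = c(0, 0), cell_size = 2)
  cfg <- discrete_config(theta_b = 0, g = 0, n_steps = 40, seed = 1)
  tr <- simulate_discrete(cfg, ramp, 2, 5, 90)     # heading +x, down the ramp
  ev <- data.frame(index = c(20L, 30L))
  h <- sensory_history_around_events(list(tr), list(ev), window = 5, n_boot = 50)
  expect_true(all(h$p_mean[h$lag < 0] < 0))
})

test_that("turn statistics by bearing peak behind the agent under attraction", {
  src <- discrete_source
  ts <- turn_stats_by_bearing(discrete_ensemble(g = -5), src, bin_width = 60)
  behind <- ts$turn_rate[abs(ts$mid) > 120]
  ahead <- ts$turn_rate[abs(ts$mid) < 60]
  expect_gt(min(behind), max(ahead))
  # without sensory coupling the profile is flat within sampling error
  ts0 <- turn_stats_by_bearing(discrete_ensemble(g = 0), src, bin_width = 60)
  expect_lt(diff(range(ts0$turn_rate)), 0.5 * mean(ts0$turn_rate))
  # doubling the map acts like strengthening the gain
  t_half <- turn_stats_by_bearing(discrete_ensemble(g = -1, factor = 1), src, bin_width = 60)
  t_dbl  <- turn_stats_by_bearing(discrete_ensemble(g = -1, factor = 2), src, bin_width = 60)
  t_gain <- turn_stats_by_bearing(discrete_ensemble(g = -2, factor = 1), src, bin_width = 60)
  behind_rate <- function(ts) mean(ts$turn_rate[abs(ts$mid) > 120], na.rm = TRUE)
  expect_gt(behind_rate(t_dbl), behind_rate(t_half))
  expect_gt(behind_rate(t_gain), behind_rate(t_half))
})
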