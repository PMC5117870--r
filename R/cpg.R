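#' Naka-Rushton spike-rate response
#'
#' Saturating map from net synaptic input to expected firing rate:
#' `m * x^n / (h^n + x^n)` for `x >= 0`, and 0 for negative input. Strictly
#' increasing on positive input and bounded by the maximal rate `m`.
#'
#' @param x net synaptic input, vectorised.
#' @param h half-response threshold (> 0); input at `h` gives `m / 2`.
#' @param m maximal rate (spikes/s, default 100).
#' @param n_exp response steepness (default 2).
#' @return firing rate in `[0, m]`.
#' @export
naka_rushton <- function(x, h, m = 100, n_exp = 2) {
  if (any(h <= 0)) stop("half-response threshold h must be > 0", call. = FALSE)
  if (m <= 0) stop("maximal rate m must be > 0", call. = FALSE)
  ifelse(x < 0, 0, m * x^n_exp / (h^n_exp + x^n_exp))
}

#' Neuromodulation of the adaptation current
#'
#' The modulatory unit converts the sensory drive `A` into the gain and time
#' constant of the slow after-hyperpolarisation (spike-rate adaptation)
#' current: `g_adapt = 6 + (0.09 A)^2` (increasing in `A`) and
#' `tau_H = 35 / (1 + 0.04 A^2)` seconds (decreasing in `A`). Stronger
#' sensory input thus deepens and speeds up adaptation, which is what lets
#' a step in `A` reshape the ongoing burst cycle.
#'
#' @param A sensory-unit firing rate (>= 0), vectorised.
#' @return list with components `g_adapt` and `tau_h`.
#' @export
neuromodulation <- function(A) {
  if (any(A < 0)) stop("A must be >= 0", call. = FALSE)
  list(g_adapt = 6 + (0.09 * A)^2, tau_h = 35 / (1 + 0.04 * A^2))
}

#' Parameters of the continuous-time CPG agent
#'
#' Two mutually inhibiting compartments (a half-center oscillator adapted
#' from lamprey locomotion models), each with an excitatory pool `E` and a
#' cross-inhibitory interneuron `C`, all with Naka-Rushton rate responses
#' and spike-rate adaptation. The rate difference `EL - ER` torques a
#' non-dimensionalized spring-mass-damper heading plant whose output is read
#' in degrees; the bearing integrates the heading and the agent advances at
#' constant speed.
#'
#' Defaults are the reference parameter set: `w_cc = w_ec = 4`,
#' `w_ce = 1/10`, `w_ee = 3`, `b_t = 19`, `tau = 1/10` s, `n_exp = 2`,
#' `m = 100`, half-response base 64, damping ratio `zeta = 1/2`, stiffness
#' `k = 1`. With these and no sensory drive the heading settles into a
#' regular oscillation of roughly ±10 degrees at about 0.3 Hz.
#'
#' @param w_ee,w_ec,w_ce,w_cc synaptic weights (>= 0): E self-excitation,
#'   C->E cross-inhibition, E->C within-compartment drive, C->C
#'   cross-inhibition.
#' @param m maximal rate (spikes/s).
#' @param n_exp Naka-Rushton steepness.
#' @param h_base base half-response threshold (64).
#' @param b_t tonic rate of the sensory unit (spikes/s).
#' @param tau membrane time constant (s).
#' @param g_sens sensory gain: spikes/s of drive per unit d(concentration)/dt.
#' @param zeta damping ratio of the heading plant.
#' @param k spring stiffness of the heading plant.
#' @param motion_scale the scale-down divisor of the bearing/position
#'   kinematics (10).
#' @param floor_A clamp the sensory unit at 0 from below (a firing rate
#'   cannot be negative); default TRUE.
#' @param adapt_tracks_own if TRUE, the adaptation variable of each `C`
#'   neuron relaxes toward that neuron's own rate rather than toward the
#'   compartment's `E` rate. Default FALSE: the reference equations have
#'   both adaptation variables of a compartment tracking `E`, and that form
#'   is kept as the default.
#' @return a `cpg_params` list.
#' @export
cpg_params <- function(w_ee = 3, w_ec = 4, w_ce = 1/10, w_cc = 4,
                       m = 100, n_exp = 2, h_base = 64, b_t = 19,
                       tau = 1/10, g_sens = 0, zeta = 1/2, k = 1,
                       motion_scale = 10, floor_A = TRUE,
                       adapt_tracks_own = FALSE) {
  for (v in list(w_ee, w_ec, w_ce, w_cc, m, n_exp, h_base, b_t, tau, g_sens, zeta, k))
    stopifnot_scalar(v, "cpg parameter")
  if (any(c(w_ee, w_ec, w_ce, w_cc) < 0)) stop("weights must be >= 0", call. = FALSE)
  if (m <= 0 || tau <= 0 || k <= 0 || zeta <= 0 || h_base <= 0)
    stop("m, tau, k, zeta and h_base must be > 0", call. = FALSE)
  structure(list(w_ee = w_ee, w_ec = w_ec, w_ce = w_ce, w_cc = w_cc,
                 m = m, n_exp = n_exp, h_base = h_base, b_t = b_t, tau = tau,
                 g_sens = g_sens, zeta = zeta, k = k, motion_scale = motion_scale,
                 floor_A = isTRUE(floor_A), adapt_tracks_own = isTRUE(adapt_tracks_own)),
            class = "cpg_params")
}

#' Reference initial state of the CPG agent
#'
#' Left excitatory pool at 80 spikes/s, right at 20 (the asymmetry kicks the
#' oscillation off), all inhibitory rates and adaptation variables at 0,
#' heading, heading velocity and bearing 0, position at the origin unless
#' overridden.
#'
#' @param x,y initial position (mm).
#' @param theta,B initial heading and bearing (degrees).
#' @return named numeric state vector.
#' @export
cpg_initial_state <- function(x = 0, y = 0, theta = 0, B = 0) {
  c(EL = 80, HEL = 0, CL = 0, HCL = 0,
    ER = 20, HER = 0, CR = 0, HCR = 0,
    theta = theta, theta_dot = 0, B = B, x = x, y = y)
}

#' Sensory drive of the continuous agent
#'
#' The input unit fires at a tonic rate plus a term proportional to the
#' temporal derivative of the sensed concentration along the path (chain
#' rule: spatial gradient dotted with velocity). Negative totals are clamped
#' to zero when `floor_A` is set (a firing rate cannot be negative).
#'
#' @param field an `odour_field` (or NULL for no odour).
#' @param x,y position (mm).
#' @param vx,vy velocity components (mm/s).
#' @param params a [cpg_params()].
#' @return firing rate of the sensory unit (spikes/s).
#' @export
sensory_drive <- function(field, x, y, vx, vy, params) {
  A <- params$b_t
  if (!is.null(field) && params$g_sens != 0) {
    gr <- field_gradient(field, x, y)
    if (is.na(gr$dx) || is.na(gr$dy))
      return(NA_real_)            # out of bounds: caller decides
    A <- A + params$g_sens * (gr$dx * vx + gr$dy * vy)
  }
  if (params$floor_A) A <- max(A, 0)
  A
}

# Right-hand side of the 13 coupled ODEs. `A_fun(t, state)` supplies the
# sensory-unit rate; heading/bearing are degrees, the plant is the
# non-dimensionalized spring-mass-damper driven by EL - ER.
cpg_rhs <- function(params, A_fun) {
  p <- params
  s10 <- p$motion_scale
  function(t, yv, parms) {
    A <- A_fun(t, yv)
    nm <- neuromodulation(A)
    gA <- nm$g_adapt; tH <- nm$tau_h
    EL <- yv[1]; HEL <- yv[2]; CL <- yv[3]; HCL <- yv[4]
    ER <- yv[5]; HER <- yv[6]; CR <- yv[7]; HCR <- yv[8]
    th <- yv[9]; thd <- yv[10]; B <- yv[11]
    R <- function(x, h) naka_rushton(x, h, m = p$m, n_exp = p$n_exp)
    dEL <- (-EL + R(A + p$w_ee * EL - p$w_ec * CR, p$h_base + gA * HEL)) / p$tau
    dHEL <- (-HEL + EL) / tH
    dCL <- (-CL + R(A + p$w_ce * EL - p$w_cc * CR, p$h_base + gA * HCL)) / p$tau
    dHCL <- (-HCL + (if (p$adapt_tracks_own) CL else EL)) / tH
    dER <- (-ER + R(A + p$w_ee * ER - p$w_ec * CL, p$h_base + gA * HER)) / p$tau
    dHER <- (-HER + ER) / tH
    dCR <- (-CR + R(A + p$w_ce * ER - p$w_cc * CL, p$h_base + gA * HCR)) / p$tau
    dHCR <- (-HCR + (if (p$adapt_tracks_own) CR else ER)) / tH
    dth <- thd
    dthd <- -2 * p$zeta * thd - p$k * th + (EL - ER)
    # B integrates the scaled-down heading and feeds the direction vector
    # directly, i.e. it is in radians; theta stays in the plant's raw units
    # (read as degrees). One half-sweep of the +-10 heading oscillation
    # advances B by about 1.1 rad, a visible zig-zag of the path.
    dB <- th / s10
    dx <- sin(B) / s10
    dy <- cos(B) / s10
    list(c(dEL, dHEL, dCL, dHCL, dER, dHER, dCR, dHCR, dth, dthd, dB, dx, dy),
         A = A)
  }
}

#' Time derivative of the CPG state
#'
#' Evaluates the right-hand side of the eight neural equations (rates and
#' adaptation variables of both compartments), the heading plant and the
#' planar kinematics at a given state and sensory drive. Exposed mainly for
#' inspection and testing; [simulate_cpg()] integrates it.
#'
#' @param state named state vector as from [cpg_initial_state()].
#' @param params a [cpg_params()].
#' @param A sensory-unit rate (spikes/s, >= 0).
#' @return named numeric vector of derivatives.
#' @export
cpg_derivatives <- function(state, params, A = params$b_t) {
  stopifnot(inherits(params, "cpg_params"))
  if (any(!is.finite(state))) stop("state must be finite", call. = FALSE)
  rhs <- cpg_rhs(params, function(t, yv) A)
  d <- rhs(0, state, NULL)[[1]]
  names(d) <- names(cpg_initial_state())
  d
}

#' Simulate the continuous-time CPG agent
#'
#' Integrates the 13 coupled ODEs (eight neural, heading, heading velocity,
#' bearing, position) with the adaptive stiff-capable `lsoda` integrator
#' (`rtol = 1e-8`, `atol = 1e-10`) and returns the solution sampled at a
#' uniform `dt`. With `g_sens = 0` the sensory unit holds its tonic rate and
#' the heading settles onto the unstimulated limit cycle. In an odour field
#' the drive follows the along-path concentration derivative; if the agent
#' leaves the arena of a bounded field the run stops at the last in-bounds
#' sample (recorded in the result).
#'
#' @param params a [cpg_params()].
#' @param field an `odour_field`, or NULL for no odour.
#' @param duration simulated time (s).
#' @param init initial state, as [cpg_initial_state()].
#' @param dt output sampling interval (s, default 0.1).
#' @param A_fun optional override of the sensory drive: function of
#'   `(t, state)` returning the rate of the input unit (used for step
#'   perturbations).
#' @param rtol,atol integrator tolerances.
#' @return a [taxis_trajectory()] with columns `t, x, y, theta, theta_dot,
#'   B, EL, ER, CL, CR, A, C`. Heading and bearing are in degrees.
#' @export
simulate_cpg <- function(params, field = NULL, duration = 200,
                         init = cpg_initial_state(), dt = 0.1, A_fun = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "cpg_params"))
  if (is.null(A_fun)) {
    if (is.null(field) || params$g_sens == 0) {
      A_fun <- function(t, yv) if (params$floor_A) max(params$b_t, 0) else params$b_t
    } else {
      A_fun <- function(t, yv) {
        s10 <- params$motion_scale
        A <- sensory_drive(field, yv[12], yv[13], sin(yv[11]) / s10, cos(yv[11]) / s10, params)
        if (is.na(A)) params$b_t else A   # outside the arena: tonic drive only
      }
    }
  }
  times <- seq(0, duration, by = dt)
  init["B"] <- deg2rad(init["B"])     # bearing integrates in radians
  sol <- deSolve::ode(y = unname(init), times = times, func = cpg_rhs(params, A_fun),
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("CPG integration failed at t = %.3f s", max(sol[, 1])), call. = FALSE)
  df <- as.data.frame(sol)
  names(df) <- c("t", "EL", "HEL", "CL", "HCL", "ER", "HER", "CR", "HCR",
                 "theta", "theta_dot", "B", "x", "y", "A")
  df$B <- rad2deg(df$B)               # reporting surface is degrees
  df$C <- if (is.null(field)) 0 else {
    v <- field_value(field, df$x, df$y)
    v
  }
  oob <- !is.null(field) & is.na(df$C)
  if (any(oob)) df <- df[seq_len(which(oob)[1] - 1L), , drop = FALSE]
  taxis_trajectory(df[, c("t", "x", "y", "theta", "theta_dot", "B",
                          "EL", "ER", "CL", "CR",
                          "HEL", "HER", "HCL", "HCR", "A", "C")],
                   config = unclass(params), model = "cpg")
}

# Times of EL burst peaks (local maxima above the series midrange) on a
# sampled trajectory; used to delimit oscillation cycles.
el_peak_times <- function(traj) {
  el <- traj$EL; t <- traj$t
  mid <- (max(el) + min(el)) / 2
  i <- which(diff(sign(diff(el))) == -2) + 1L
  i <- i[el[i] > mid]
  t[i]
}

#' Oscillation summary of an unstimulated run
#'
#' Peak frequency of the heading-velocity spectrum and mean per-cycle
#' heading amplitude (half peak-to-peak, degrees) after discarding an
#' initial transient. Cycles are delimited by EL burst peaks.
#'
#' @param traj a CPG [taxis_trajectory()].
#' @param transient seconds to discard.
#' @return list with `frequency_hz`, `amplitude_deg`, `period_s`.
#' @export
cpg_oscillation_summary <- function(traj, transient = 50) {
  post <- traj[traj$t >= transient, , drop = FALSE]
  dt <- stats::median(diff(post$t))
  spec <- heading_speed_spectrum(list(post), dt = dt)
  f_peak <- spectrum_peak(spec)
  pk <- el_peak_times(post)
  if (length(pk) < 3) stop("no stable cycle detected", call. = FALSE)
  amps <- vapply(seq_len(length(pk) - 1L), function(i) {
    th <- post$theta[post$t >= pk[i] & post$t < pk[i + 1L]]
    (max(th) - min(th)) / 2
  }, numeric(1))
  list(frequency_hz = f_peak, amplitude_deg = mean(amps),
       period_s = mean(diff(pk)))
}

#' Net bearing change caused by a step perturbation
#'
#' Runs the oscillator to its limit cycle, then applies a bilateral step of
#' amplitude `a_m` to the sensory unit at time `t_s` and measures the net
#' change of bearing attributable to the perturbation: the bearing
#' difference between the perturbed and unperturbed runs once the perturbed
#' oscillation has settled back to zero-mean bearing drift (per-cycle drift
#' difference below `drift_tol`). Zero amplitude returns exactly 0.
#'
#' @param params a [cpg_params()].
#' @param a_m step amplitude (spikes/s, signed).
#' @param t_s onset time (s); should follow the transient.
#' @param settle seconds simulated after onset (default 60).
#' @param drift_tol per-cycle bearing drift tolerance (degrees).
#' @param init initial state.
#' @param dt sampling interval (s).
#' @param unpert optional precomputed unperturbed run (same `params`,
#'   `init`, `dt`, covering at least `t_s + settle`); avoids recomputing the
#'   reference when sweeping many onset times.
#' @return net bearing change (degrees).
#' @export
step_response_bearing_change <- function(params, a_m, t_s, settle = 60,
                                         drift_tol = 0.05,
                                         init = cpg_initial_state(), dt = 0.05,
                                         unpert = NULL) {
  stopifnot(inherits(params, "cpg_params"))
  if (a_m == 0) return(0)
  horizon <- t_s + settle
  base_A <- if (params$floor_A) max(params$b_t, 0) else params$b_t
  A_pert <- function(t, yv) {
    A <- params$b_t + if (t >= t_s) a_m else 0
    if (params$floor_A) max(A, 0) else A
  }
  if (is.null(unpert))
    unpert <- simulate_cpg(params, NULL, horizon, init = init, dt = dt,
                           A_fun = function(t, yv) base_A)
  if (max(unpert$t) < horizon - dt / 2)
    stop("unperturbed reference run is shorter than t_s + settle", call. = FALSE)
  pert <- simulate_cpg(params, NULL, horizon, init = init, dt = dt, A_fun = A_pert)
  # Once the heading oscillation is back on a (possibly shifted) limit cycle
  # the mean heading is zero, so the bearing converges to a constant plus a
  # bounded oscillation; averaging over whole cycles removes the latter.
  # Settling = successive per-cycle bearing means no longer drift.
  cycle_mean_B <- function(traj) {
    pk <- el_peak_times(traj[traj$t >= t_s + settle / 2, , drop = FALSE])
    if (length(pk) < 3)
      stop("no stable cycle after perturbation within the horizon", call. = FALSE)
    means <- vapply(seq_len(length(pk) - 1L), function(i) {
      mean(traj$B[traj$t >= pk[i] & traj$t < pk[i + 1L]])
    }, numeric(1))
    k <- length(means)
    if (k >= 2 && abs(means[k] - means[k - 1L]) > drift_tol)
      warning("bearing drift not fully settled within the horizon")
    means[k]
  }
  cycle_mean_B(pert) - cycle_mean_B(unpert)
}

#' Phase-response curve of the CPG agent
#'
#' Tabulates the net bearing change produced by a bilateral sensory step as
#' a function of the oscillator phase at onset, for one or more step
#' amplitudes. Phase 0 is an EL burst peak (after the transient) and phase 1
#' the next; onset times are spread uniformly across that cycle.
#'
#' @param params a [cpg_params()].
#' @param amplitudes step amplitudes (spikes/s). Steps more negative than
#'   about -2 push the oscillator onto a slow asymmetric cycle whose bearing
#'   drifts indefinitely; there the net bearing change is ill-defined and a
#'   warning is raised.
#' @param n_points onsets per cycle (reference figure uses 102).
#' @param transient seconds run before the reference cycle.
#' @param settle seconds simulated after each onset.
#' @return data frame with columns `phase`, `t_s`, `a_m`, `delta_b_deg`.
#' @export
phase_response_curve <- function(params, amplitudes = c(-2, 2), n_points = 102,
                                 transient = 60, settle = 60) {
  dt <- 0.05
  base_A <- if (params$floor_A) max(params$b_t, 0) else params$b_t
  horizon <- transient + 30 + settle
  unpert <- simulate_cpg(params, NULL, horizon, dt = dt,
                         A_fun = function(t, yv) base_A)
  pk <- el_peak_times(unpert[unpert$t >= transient & unpert$t <= transient + 30, , drop = FALSE])
  if (length(pk) < 2) stop("no stable cycle detected", call. = FALSE)
  t0 <- pk[1]; period <- pk[2] - pk[1]
  phases <- seq(0, 1, length.out = n_points)
  grid <- expand.grid(phase = phases, a_m = amplitudes)
  grid$t_s <- t0 + grid$phase * period
  grid$delta_b_deg <- vapply(seq_len(nrow(grid)), function(i) {
    step_response_bearing_change(params, grid$a_m[i], grid$t_s[i], settle = settle,
                                 dt = dt, unpert = unpert)
  }, numeric(1))
  grid[, c("phase", "t_s", "a_m", "delta_b_deg")]
}

#' Limit-cycle state of the unstimulated oscillator
#'
#' Runs the oscillator without odour for `settle` seconds and returns the
#' final state with position and bearing re-assigned, so taxis experiments
#' can start from the settled rhythm rather than the reference initial
#' conditions (whose strong left-right asymmetry produces a large opening
#' swing).
#'
#' @param params a [cpg_params()].
#' @param settle settling time (s, default 120).
#' @param x,y start position (mm).
#' @param B start bearing (degrees).
#' @return named state vector usable as `init` of [simulate_cpg()].
#' @export
cpg_settled_state <- function(params, settle = 120, x = 0, y = 0, B = 0) {
  base <- simulate_cpg(params, NULL, settle, dt = 0.1)
  last <- as.data.frame(base)[nrow(base), ]
  c(EL = last$EL, HEL = last$HEL, CL = last$CL, HCL = last$HCL,
    ER = last$ER, HER = last$HER, CR = last$CR, HCR = last$HCR,
    theta = last$theta, theta_dot = last$theta_dot, B = B, x = x, y = y)
}

#' Heading-plant derivatives
#'
#' The idealized torsional spring-mass-damper that converts the rate
#' difference of the two excitatory pools into heading dynamics:
#' `d(theta)/dt = theta_dot`,
#' `d(theta_dot)/dt = -2 zeta theta_dot - k theta + (e_l - e_r)`.
#' With a constant drive the fixed point is `theta = (e_l - e_r) / k`.
#'
#' @param theta,theta_dot heading (plant units, read as degrees) and its
#'   rate.
#' @param e_l,e_r left/right excitatory rates (spikes/s).
#' @param zeta damping ratio.
#' @param k spring stiffness.
#' @return named vector `c(dtheta, dtheta_dot)`.
#' @export
heading_plant_derivatives <- function(theta, theta_dot, e_l, e_r,
                                      zeta = 1/2, k = 1) {
  c(dtheta = theta_dot,
    dtheta_dot = -2 * zeta * theta_dot - k * theta + (e_l - e_r))
}

#' Bearing and position derivatives
#'
#' The scaled-down planar kinematics: the bearing integrates the heading
#' (`dB/dt = theta / motion_scale`, radians) and the agent advances along
#' the bearing at constant speed `1 / motion_scale`, so the planar speed is
#' exactly `1 / motion_scale` at all times.
#'
#' @param theta heading (plant units).
#' @param B bearing (radians).
#' @param motion_scale scale-down divisor (10).
#' @return named vector `c(dB, dx, dy)`.
#' @export
kinematics_derivatives <- function(theta, B, motion_scale = 10) {
  c(dB = theta / motion_scale,
    dx = sin(B) / motion_scale,
    dy = cos(B) / motion_scale)
}
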