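#' Hard-limit function for re-orientation amplitude
#'
#' Clips a turn amplitude to the physically meaningful range `[0, pi]`
#' radians: the lower bound prevents a left turn from becoming a right turn
#' (or vice versa), the upper bound is the maximal re-orientation a larva's
#' body bend permits (a U-turn). Idempotent and non-decreasing.
#'
#' @param x turn amplitude (radians), vectorised.
#' @return `x` clipped to `[0, pi]`.
#' @export
hard_limit <- function(x) {
  if (any(!is.finite(x))) stop("hard_limit needs finite input", call. = FALSE)
  pmin(pmax(x, 0), pi)
}

#' Configuration of the discrete-time oscillatory agent
#'
#' At every step the point agent rotates on the spot by an amplitude that
#' alternates left/right, then advances a fixed distance. The amplitude is
#' the baseline `theta_b` plus a linear sensory modulation
#' `g * (s_t + p)` where `p` is the concentration change perceived over the
#' previous step, all passed through [hard_limit()]. A negative gain makes
#' increasing concentration straighten the path and decreasing concentration
#' enlarge the turn (up to a U-turn): attraction. A positive gain yields
#' aversion; zero gain, neither.
#'
#' Angles are taken in degrees here (the reporting surface) and converted to
#' radians internally. One step is one second, matching the fixed step
#' length of 1 mm to the nominal 1 mm/s crawl speed.
#'
#' @param theta_b baseline turn amplitude (degrees, default 10).
#' @param g sensorimotor gain (radians of turn per unit concentration,
#'   signed; negative = attraction). The gain multiplies a concentration,
#'   so unlike the angular parameters it is not a degree-valued surface.
#' @param s_t tonic sensory term (concentration units, default 0).
#' @param lambda_step step length (mm, default 1).
#' @param noise_sigma std of additive heading noise per step (degrees,
#'   default 0). Noise is added outside the hard limit, so it can flip the
#'   effective turn direction.
#' @param n_steps number of steps to simulate.
#' @param seed RNG seed for noise and boundary resets.
#' @return a `discrete_config` list.
#' @export
discrete_config <- function(theta_b = 10, g = 0, s_t = 0, lambda_step = 1,
                            noise_sigma = 0, n_steps = 800, seed = 1L) {
  for (v in list(theta_b, g, s_t, lambda_step, noise_sigma)) stopifnot_scalar(v, "config field")
  if (lambda_step <= 0) stop("lambda_step must be > 0", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (theta_b < 0 || theta_b > 180) stop("theta_b must lie in [0, 180] degrees", call. = FALSE)
  structure(list(theta_b = theta_b, g = g, s_t = s_t, lambda_step = lambda_step,
                 noise_sigma = noise_sigma, n_steps = as.integer(n_steps),
                 seed = as.integer(seed)),
            class = "discrete_config")
}

# Resample the heading uniformly among orientations whose next step stays in
# bounds; the position is left unchanged. Rejection sampling against the
# arena; errors out if no orientation at 1-degree resolution is feasible.
boundary_reset <- function(x, y, lambda_step, field) {
  cand <- deg2rad(0:359)
  feas <- !field_oob(field, x + lambda_step * sin(cand), y + lambda_step * cos(cand))
  if (!any(feas)) stop("boundary reset failed: no in-bounds orientation (degenerate arena)",
                       call. = FALSE)
  repeat {
    th <- stats::runif(1, 0, 2 * pi)
    if (!field_oob(field, x + lambda_step * sin(th), y + lambda_step * cos(th)))
      return(th)
  }
}

#' Simulate the discrete-time oscillatory agent
#'
#' Runs the state-update loop in its strict order: (1) heading update by the
#' hard-limited, sensory-modulated alternating turn (plus optional Gaussian
#' noise), (2-3) a forward step of `lambda_step` mm along the new heading
#' (compass convention: heading 0 points along +y, increasing toward +x),
#' (4-5) sensing of the concentration at the new position and of its
#' one-step change. Initial sensed concentration is 0, so the first step's
#' modulation is driven by `s_t` alone. If a step would leave the arena the
#' heading is re-assigned uniformly at random among orientations that keep
#' the agent in bounds (position unchanged) before moving.
#'
#' @param cfg a [discrete_config()].
#' @param field an `odour_field`.
#' @param x0,y0 initial position (mm).
#' @param theta0 initial heading (degrees).
#' @return a [taxis_trajectory()] with one row per step (plus the initial
#'   state at `t = 0`); column `turn` holds the applied re-orientation
#'   (signed, post-limit, pre-noise, radians).
#' @export
simulate_discrete <- function(cfg, field, x0 = 0, y0 = 0, theta0 = 0) {
  stopifnot(inherits(cfg, "discrete_config"), inherits(field, "odour_field"))
  set.seed(cfg$seed)
  n_steps <- cfg$n_steps
  theta_b <- deg2rad(cfg$theta_b)
  g <- cfg$g                          # radians of turn per concentration unit
  sigma_z <- deg2rad(cfg$noise_sigma)
  lam <- cfg$lambda_step

  x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
  th <- numeric(n_steps + 1); s <- numeric(n_steps + 1)
  p <- numeric(n_steps + 1); turn <- numeric(n_steps + 1)
  reset <- logical(n_steps + 1)
  x[1] <- x0; y[1] <- y0; th[1] <- deg2rad(theta0)
  s[1] <- 0; p[1] <- 0; turn[1] <- 0   # s0 = 0 initial condition

  if (field_oob(field, x0, y0))
    stop("initial position lies outside the arena", call. = FALSE)

  for (n in seq_len(n_steps)) {
    i <- n + 1L
    amp <- hard_limit(theta_b + g * (cfg$s_t + p[i - 1L]))
    dir <- if (n %% 2L == 0L) 1 else -1       # (-1)^n alternation
    turn[i] <- amp * dir
    th_new <- th[i - 1L] + turn[i]
    if (sigma_z > 0) th_new <- th_new + stats::rnorm(1, 0, sigma_z)
    xn <- x[i - 1L] + lam * sin(th_new)
    yn <- y[i - 1L] + lam * cos(th_new)
    if (field_oob(field, xn, yn)) {
      th_new <- boundary_reset(x[i - 1L], y[i - 1L], lam, field)
      xn <- x[i - 1L] + lam * sin(th_new)
      yn <- y[i - 1L] + lam * cos(th_new)
      reset[i] <- TRUE
    }
    th[i] <- th_new; x[i] <- xn; y[i] <- yn
    s[i] <- field_value(field, xn, yn)
    p[i] <- s[i] - s[i - 1L]
  }

  taxis_trajectory(
    data.frame(t = 0:n_steps, x = x, y = y, theta = th, s = s, p = p,
               turn = turn, reset = reset),
    config = unclass(cfg), seed = cfg$seed, model = "discrete")
}

#' Simulate an ensemble of discrete agents
#'
#' Each agent gets an independent seed derived from the master seed via
#' [split_seeds()] and, by default, a random start position (uniform in the
#' central half of the arena) and orientation.
#'
#' @param cfg a [discrete_config()]; its `seed` is the master seed.
#' @param field an `odour_field` with defined bounds.
#' @param n_agents ensemble size.
#' @param starts optional data frame with columns `x`, `y`, `theta_deg`
#'   overriding the random starts.
#' @return list of [taxis_trajectory()] objects.
#' @export
simulate_discrete_ensemble <- function(cfg, field, n_agents = 30, starts = NULL) {
  seeds <- split_seeds(cfg$seed, n_agents + 1L)
  if (is.null(starts)) {
    lims <- arena_limits(field)
    set.seed(seeds[n_agents + 1L])
    cx <- mean(lims$xlim); cy <- mean(lims$ylim)
    wx <- diff(lims$xlim) / 4; wy <- diff(lims$ylim) / 4
    starts <- data.frame(x = stats::runif(n_agents, cx - wx, cx + wx),
                         y = stats::runif(n_agents, cy - wy, cy + wy),
                         theta_deg = stats::runif(n_agents, -180, 180))
  }
  lapply(seq_len(n_agents), function(i) {
    ci <- cfg; ci$seed <- seeds[i]
    simulate_discrete(ci, field, starts$x[i], starts$y[i], starts$theta_deg[i])
  })
}

arena_limits <- function(field) {
  if (inherits(field, "grid_field")) {
    nx <- nrow(field$values); ny <- ncol(field$values)
    list(xlim = field$origin[1] + c(0, (nx - 1) * field$cell_size),
         ylim = field$origin[2] + c(0, (ny - 1) * field$cell_size))
  } else if (!is.null(field$xlim) && !is.null(field$ylim)) {
    list(xlim = field$xlim, ylim = field$ylim)
  } else stop("field has no arena bounds; supply explicit start positions", call. = FALSE)
}
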