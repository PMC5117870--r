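#' Reference odour arenas
#'
#' The two default study environments used throughout the documentation,
#' tests and reproduction scripts. The absolute concentration scale of the
#' recorded odour maps behind the published experiments is not available,
#' so concentration units here are arbitrary; what is fixed is the regime
#' each amplitude puts the reference agent into.
#'
#' \describe{
#'   \item{`discrete`}{An isotropic Gaussian source (`sigma` 10 mm) centred
#'     in a 100 x 100 mm arena with reflecting-by-reassignment boundaries.
#'     Amplitude `c = 5e3`: at the reference attractive gain `g = -5` the
#'     strongest one-step sensory signal (one step past the radius of
#'     maximal gradient) modulates the re-orientation up to about 140
#'     degrees, so the >30 and >90 degree turn events scored in the
#'     analyses occur while an unsaturated orbital zone remains beyond
#'     about 1.5 sigma.}
#'   \item{`cpg`}{An unbounded Gaussian source with the continuous model's
#'     reference shape (`sigma` 10, correlation 1/5) centred at the origin.
#'     Amplitude `c = 2e4`: at the reference gain `g_sens = 70` the
#'     closed-loop drive perturbations reach several spikes/s — the scale
#'     at which step inputs measurably deflect the bearing — which puts
#'     `g_sens = 70` in the orbital and `g_sens = 140` in the crossing-over
#'     regime.}
#' }
#'
#' @param model `"discrete"` or `"cpg"`.
#' @param factor optional extra scaling of the map (stimulus-intensity
#'   manipulations), passed to [scale_field()].
#' @return an `odour_field`.
#' @export
reference_field <- function(model = c("discrete", "cpg"), factor = 1) {
  model <- match.arg(model)
  f <- if (model == "discrete") {
    gaussian_field(50, 50, 10, 10, rho = 0, c = 5e3,
                   xlim = c(0, 100), ylim = c(0, 100))
  } else {
    gaussian_field(0, 0, 10, 10, rho = 1/5, c = 2e4)
  }
  scale_field(f, factor)
}

#' Orbital persistence of a trajectory around a source
#'
#' Circulation consistency of the path around the source: the absolute net
#' winding divided by the total absolute winding of the source-relative
#' polar angle, over the post-transient part of the trajectory. A perfect
#' orbit scores 1; crossing-over paths, which pass the source and reverse
#' their circulation, score toward 0.
#'
#' @param traj a [taxis_trajectory()].
#' @param source `c(x, y)` (mm).
#' @param t_min discard samples before this time (s).
#' @return value in `[0, 1]`.
#' @export
orbital_persistence <- function(traj, source = c(0, 0), t_min = 0) {
  post <- traj[traj$t >= t_min, , drop = FALSE]
  phi <- atan2(post$y - source[2], post$x - source[1])
  dphi <- atan2(sin(diff(phi)), cos(diff(phi)))
  tot <- sum(abs(dphi))
  if (tot == 0) return(NA_real_)
  abs(sum(dphi)) / tot
}
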