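#' Angle helpers
#'
#' Conversions between degrees and radians, and wrapping of angles to the
#' half-open interval (-180, 180] degrees (ties at the half-turn map to +180).
#' All bearing-like quantities reported by this package use that convention.
#'
#' @param x numeric vector of angles.
#' @return numeric vector of the same length.
#' @keywords internal
#' @name angles
NULL

#' @rdname angles
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname angles
#' @export
rad2deg <- function(x) x * 180 / pi

#' @rdname angles
#' @export
wrap_deg <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  # floor maps +180 to -180; the convention here keeps +180
  w[w == -180] <- 180
  w
}

#' @rdname angles
#' @export
wrap_rad <- function(x) deg2rad(wrap_deg(rad2deg(x)))

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

#' Derive independent per-agent seeds from a master seed
#'
#' Ensemble runs give each agent its own RNG stream so results do not depend
#' on execution order. Seeds are drawn once from the master seed.
#'
#' @param master_seed single integer.
#' @param n number of seeds.
#' @return integer vector of length `n`, all below 2^31.
#' @export
split_seeds <- function(master_seed, n) {
  stopifnot_scalar(master_seed)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}
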