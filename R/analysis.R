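#' Mean amplitude spectrum of heading velocity
#'
#' Computes the discrete Fourier transform of each trajectory's
#' heading-velocity series (sampled uniformly at `dt`) and averages the
#' magnitude spectra across trajectories. No taper is applied, so spectral
#' leakage is as for a raw DFT. The heading-velocity channel is
#' `theta_dot` when present (continuous agent), otherwise the first
#' difference of `theta` divided by `dt`.
#'
#' @param trajectories list of [taxis_trajectory()] objects (or data frames
#'   with a `t` and a heading channel).
#' @param dt sampling interval (s, default 0.1).
#' @param demean subtract each series' mean before transforming (default
#'   TRUE, so the zero bin reflects only residual drift).
#' @return object of class `spectrum_result`: list with `frequency` (Hz, up
#'   to Nyquist), `mean_amplitude`, `per_trajectory` (matrix, one column per
#'   trajectory) and `dt`.
#' @export
heading_speed_spectrum <- function(trajectories, dt = 0.1, demean = TRUE) {
  stopifnot(length(trajectories) >= 1)
  series <- lapply(trajectories, function(tr) {
    tt <- tr$t
    if (max(abs(diff(tt) - stats::median(diff(tt)))) > 1e-6)
      stop("trajectory is not uniformly sampled", call. = FALSE)
    if (!is.null(tr$theta_dot)) tr$theta_dot else diff(tr$theta) / dt
  })
  n <- unique(vapply(series, length, integer(1)))
  if (length(n) != 1)
    stop("all trajectories must have the same length", call. = FALSE)
  nf <- n %/% 2L
  amps <- vapply(series, function(v) {
    if (demean) v <- v - mean(v)
    (Mod(stats::fft(v)) / n)[seq_len(nf)]
  }, numeric(nf))
  structure(list(frequency = (seq_len(nf) - 1) / (n * dt),
                 mean_amplitude = rowMeans(amps),
                 per_trajectory = amps, dt = dt),
            class = "spectrum_result")
}

#' Peak frequency of a spectrum
#'
#' @param spec a `spectrum_result`.
#' @param f_min ignore bins below this frequency (Hz); excludes the DC bin
#'   by default.
#' @return frequency (Hz) of the largest mean amplitude.
#' @export
spectrum_peak <- function(spec, f_min = 0.01) {
  keep <- spec$frequency >= f_min
  spec$frequency[keep][which.max(spec$mean_amplitude[keep])]
}

# Per-step turn magnitudes in degrees. Discrete agent: the realized
# per-step heading change (noise included; boundary-reset steps excluded) —
# the observable re-orientation, which with noise off equals the applied
# turn. Continuous agent: net heading change between successive zero
# crossings of heading velocity (one half-sweep), assigned to the crossing
# sample, so the same angular thresholds apply to both agents.
turn_series <- function(traj) {
  if (!is.null(traj$turn)) {
    n <- nrow(traj)
    if (n < 2) return(data.frame(index = integer(), t = numeric(), turn_deg = numeric()))
    idx <- 2:n
    dth <- wrap_deg(rad2deg(diff(traj$theta)))
    keep <- if (!is.null(traj$reset)) !traj$reset[idx] else rep(TRUE, length(idx))
    data.frame(index = idx[keep], t = traj$t[idx][keep], turn_deg = dth[keep])
  } else {
    v <- traj$theta_dot
    cross <- which(v[-1] * v[-length(v)] < 0)
    if (length(cross) < 2) return(data.frame(index = integer(), t = numeric(), turn_deg = numeric()))
    seg_end <- cross[-1]
    seg_start <- cross[-length(cross)]
    data.frame(index = seg_end, t = traj$t[seg_end],
               turn_deg = traj$theta[seg_end] - traj$theta[seg_start])
  }
}

#' Detect turn events with the two printed exclusion rules
#'
#' Events are steps (discrete agent) or half-sweeps (continuous agent)
#' whose re-orientation magnitude exceeds `large_threshold` degrees. For
#' the discrete agent the re-orientation is the realized per-step heading
#' change — noise included, boundary resets excluded — which is what an
#' observer of the trajectory would score (and equals the applied turn when
#' noise is off). Two
#' flags implement the two rules used for turn statistics:
#' \describe{
#'   \item{`is_large`}{magnitude above threshold AND not followed by another
#'     above-threshold turn at the next step — the rule for turn-rate /
#'     turn-angle statistics.}
#'   \item{`is_first`}{magnitude above threshold AND not preceded by an
#'     above-threshold turn at the previous step — the rule for first-turn
#'     bias.}
#' }
#' `is_huge` marks events above `huge_threshold` (used for sensory-history
#' averaging around the sharpest re-orientations).
#'
#' @param traj a [taxis_trajectory()].
#' @param large_threshold degrees (default 30).
#' @param huge_threshold degrees (default 90).
#' @param source optional `c(x, y)` of the odour source, to annotate
#'   bearing at onset.
#' @return data frame of events: `index`, `t`, `magnitude_deg` (unsigned),
#'   `direction` (+1 right / -1 left), `p_before`, `bearing_deg` (at the
#'   preceding sample, if `source` given), `is_large`, `is_first`,
#'   `is_huge`.
#' @export
detect_turns <- function(traj, large_threshold = 30, huge_threshold = 90,
                         source = NULL) {
  ts <- turn_series(traj)
  mag <- abs(ts$turn_deg)
  big <- mag > large_threshold
  nxt <- c(big[-1], FALSE)           # is the following turn large?
  prv <- c(FALSE, big[-length(big)]) # was the previous turn large?
  keep <- which(big)
  ev <- data.frame(index = ts$index[keep], t = ts$t[keep],
                   magnitude_deg = mag[keep],
                   direction = sign(ts$turn_deg[keep]),
                   p_before = rep(NA_real_, length(keep)),
                   bearing_deg = rep(NA_real_, length(keep)),
                   is_large = big[keep] & !nxt[keep],
                   is_first = big[keep] & !prv[keep],
                   is_huge = mag[keep] > huge_threshold)
  if (nrow(ev) > 0 && !is.null(traj$p))
    ev$p_before <- traj$p[pmax(ev$index - 1L, 1L)]
  if (nrow(ev) > 0 && !is.null(source)) {
    b <- bearing_to_source(traj, source)
    ev$bearing_deg <- b[pmax(ev$index - 1L, 1L)]
  }
  ev
}

#' Signed bearing to the odour source
#'
#' Angle between the agent's heading and the agent-to-source direction,
#' wrapped to (-180, 180] degrees with the half-turn tie mapped to +180.
#' Zero means the odour is dead ahead; positive means the odour lies on the
#' agent's right.
#'
#' @param traj a [taxis_trajectory()] (heading in radians for the discrete
#'   agent, degrees for the continuous agent; handled automatically). The
#'   continuous agent's direction of travel is its bearing channel `B`.
#' @param source length-2 numeric `c(x, y)` (mm).
#' @return numeric vector of bearings (degrees); `NA` where the agent sits
#'   exactly on the source.
#' @export
bearing_to_source <- function(traj, source) {
  stopifnot(length(source) == 2L)
  dx <- source[1] - traj$x
  dy <- source[2] - traj$y
  at_source <- dx == 0 & dy == 0
  # compass angle of the source direction (0 = +y, clockwise-positive
  # toward +x) minus the heading, so positive = source to the right
  src <- rad2deg(atan2(dx, dy))
  head_deg <- if (identical(attr(traj, "model"), "cpg")) traj$B else rad2deg(traj$theta)
  b <- wrap_deg(src - head_deg)
  b[at_source] <- NA_real_
  b
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bearing-to-source occupancy histogram
#'
#' Pools bearing samples from an ensemble into equal-width bins over
#' (-180, 180] and normalises to unit mass. Optional subset filters restrict
#' to samples whose instantaneous turn magnitude is below a cut (the
#' "orbital" subset) and/or whose radial distance to the source lies in a
#' range.
#'
#' @param trajectories list of trajectories.
#' @param source `c(x, y)` (mm).
#' @param bins number of bins (default 36, i.e. 10-degree bins).
#' @param max_turn_deg keep only samples with applied turn magnitude below
#'   this (degrees); NULL for no filter.
#' @param min_distance,max_distance radial distance filter (mm).
#' @return data frame `mid` (bin centre, degrees), `density` (sums to 1),
#'   `count`; attribute `n_samples`. Empty subsets yield zero counts and an
#'   `empty` attribute set to TRUE.
#' @export
bearing_distribution <- function(trajectories, source, bins = 36,
                                 max_turn_deg = NULL,
                                 min_distance = NULL, max_distance = NULL) {
  breaks <- seq(-180, 180, length.out = bins + 1L)
  pool <- unlist(lapply(trajectories, function(tr) {
    b <- bearing_to_source(tr, source)
    keep <- !is.na(b)
    if (!is.null(max_turn_deg) && !is.null(tr$turn)) {
      step_turn <- c(0, abs(wrap_deg(rad2deg(diff(tr$theta)))))
      keep <- keep & step_turn < max_turn_deg
    }
    d <- sqrt((tr$x - source[1])^2 + (tr$y - source[2])^2)
    if (!is.null(min_distance)) keep <- keep & d >= min_distance
    if (!is.null(max_distance)) keep <- keep & d <= max_distance
    b[keep]
  }))
  # (-180, 180] binning: samples at exactly -180 were wrapped to +180 already
  cnt <- as.vector(table(cut(pool, breaks, include.lowest = FALSE, right = TRUE)))
  out <- data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    count = cnt,
                    density = if (sum(cnt) > 0) cnt / sum(cnt) else rep(0, bins))
  attr(out, "n_samples") <- sum(cnt)
  attr(out, "empty") <- sum(cnt) == 0
  out
}

#' Bearings of the two histogram modes
#'
#' Finds the modal bin among positive and among negative bearings of a
#' [bearing_distribution()]. For an attractive gain the discrete agent
#' orbits the source, putting the modes near +90 and -90 degrees.
#'
#' @param dist a bearing distribution data frame.
#' @return list with `mode_pos`, `mode_neg` (bin centres, degrees) and
#'   `mean_abs` — the mean absolute bearing of the two modes.
#' @export
bearing_modes <- function(dist) {
  pos <- dist[dist$mid > 0, ]; neg <- dist[dist$mid < 0, ]
  mp <- pos$mid[which.max(pos$count)]
  mn <- neg$mid[which.max(neg$count)]
  list(mode_pos = mp, mode_neg = mn, mean_abs = mean(abs(c(mp, mn))))
}

#' First-turn bias toward the odour side
#'
#' Over all first-turn events (above-threshold turns not preceded by one),
#' classifies each as correct (directed toward the side the odour lies on
#' at onset) or wrong, and stratifies mean turn direction by bearing bin.
#' Events with the odour dead ahead or dead astern are unclassifiable and
#' excluded from the probabilities (but counted).
#'
#' @param trajectories list of trajectories.
#' @param source `c(x, y)` (mm).
#' @param large_threshold degrees (default 30).
#' @param bearing_bins number of bins for the stratification (default 12).
#' @return list with `p_correct`, `p_wrong` (summing to 1 over classified
#'   events), `n_events`, `n_classified`, and `by_bearing` (data frame of
#'   mean signed turn direction per bearing bin).
#' @export
first_turn_bias <- function(trajectories, source, large_threshold = 30,
                            bearing_bins = 12) {
  evs <- do.call(rbind, lapply(trajectories, function(tr)
    detect_turns(tr, large_threshold = large_threshold, source = source)))
  evs <- evs[evs$is_first & !is.na(evs$bearing_deg), , drop = FALSE]
  if (nrow(evs) == 0)
    return(list(p_correct = NA_real_, p_wrong = NA_real_, n_events = 0L,
                n_classified = 0L, by_bearing = NULL))
  side <- sign(evs$bearing_deg) * (abs(evs$bearing_deg) %% 180 != 0)
  classified <- side != 0
  correct <- sign(evs$direction[classified]) == side[classified]
  breaks <- seq(-180, 180, length.out = bearing_bins + 1L)
  bin <- cut(evs$bearing_deg, breaks, include.lowest = TRUE)
  by_bearing <- stats::aggregate(list(mean_direction = evs$direction),
                                 by = list(bin = bin), FUN = mean)
  by_bearing$mid <- ((breaks[-length(breaks)] + breaks[-1]) / 2)[match(by_bearing$bin, levels(bin))]
  list(p_correct = mean(correct), p_wrong = 1 - mean(correct),
       n_events = nrow(evs), n_classified = sum(classified),
       by_bearing = by_bearing[, c("bin", "mid", "mean_direction")])
}

#' Preference index of an ensemble
#'
#' `(N_odour_side - N_other_side) / N_total` over agent positions at an
#' evaluation time, the arena being split by a vertical or horizontal
#' midline; the odour side is the half containing the source. Agents
#' exactly on the midline count to neither side but remain in the total.
#'
#' @param trajectories list of trajectories.
#' @param source `c(x, y)` (mm).
#' @param midline value of the splitting line coordinate.
#' @param axis `"x"` (vertical midline) or `"y"`.
#' @param t_eval evaluation time (s); defaults to each trajectory's end.
#' @return preference index in `[-1, 1]`.
#' @export
preference_index <- function(trajectories, source, midline, axis = c("x", "y"),
                             t_eval = NULL) {
  axis <- match.arg(axis)
  pos <- vapply(trajectories, function(tr) {
    i <- if (is.null(t_eval)) nrow(tr) else which.min(abs(tr$t - t_eval))
    tr[[axis]][i]
  }, numeric(1))
  src <- if (axis == "x") source[1] else source[2]
  s_side <- sign(src - midline)
  if (s_side == 0) stop("source lies on the midline", call. = FALSE)
  (sum(sign(pos - midline) == s_side) - sum(sign(pos - midline) == -s_side)) /
    length(pos)
}

#' Event-aligned sensory history
#'
#' Averages the sensed concentration `s` and its one-step change `p` in a
#' window around event times, with nonparametric bootstrap 95% confidence
#' intervals, optionally split by the sign of the first post-event `p`.
#' Events whose window exceeds the trajectory bounds are dropped (count
#' reported).
#'
#' @param trajectories list of trajectories (discrete agent: `s`, `p`
#'   channels).
#' @param events list of event data frames (as from [detect_turns()]),
#'   parallel to `trajectories`; rows used are all events present.
#' @param window steps before/after the event (default 10).
#' @param split_by_post_p if TRUE, also return averages over the subsets
#'   with positive / negative first post-event `p`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return list with `lag` (steps), `s_mean`, `s_lo`, `s_hi`, `p_mean`,
#'   `p_lo`, `p_hi`, `n_events`, `n_dropped`, and if requested `pos`/`neg`
#'   sublists of the same shape.
#' @export
sensory_history_around_events <- function(trajectories, events, window = 10,
                                          split_by_post_p = FALSE,
                                          n_boot = 1000, seed = 1L) {
  lag <- -window:window
  rows_s <- list(); rows_p <- list(); post_sign <- numeric(0)
  dropped <- 0L
  for (k in seq_along(trajectories)) {
    tr <- trajectories[[k]]; ev <- events[[k]]
    if (is.null(ev) || nrow(ev) == 0) next
    for (i in ev$index) {
      if (i - window < 1L || i + window > nrow(tr)) { dropped <- dropped + 1L; next }
      rows_s[[length(rows_s) + 1L]] <- tr$s[i + lag]
      rows_p[[length(rows_p) + 1L]] <- tr$p[i + lag]
      post_sign <- c(post_sign, sign(tr$p[min(i + 1L, nrow(tr))]))
    }
  }
  if (length(rows_s) == 0)
    return(list(lag = lag, n_events = 0L, n_dropped = dropped))
  S <- do.call(rbind, rows_s); P <- do.call(rbind, rows_p)
  summarise <- function(S, P) {
    set.seed(seed)
    boot_ci <- function(M) {
      if (nrow(M) == 1) return(rbind(M[1, ], M[1, ]))
      idx <- matrix(sample.int(nrow(M), nrow(M) * n_boot, replace = TRUE), ncol = n_boot)
      bm <- apply(idx, 2, function(j) colMeans(M[j, , drop = FALSE]))
      apply(bm, 1, stats::quantile, probs = c(0.025, 0.975))
    }
    cs <- boot_ci(S); cp <- boot_ci(P)
    list(lag = lag, s_mean = colMeans(S), s_lo = cs[1, ], s_hi = cs[2, ],
         p_mean = colMeans(P), p_lo = cp[1, ], p_hi = cp[2, ],
         n_events = nrow(S), n_dropped = dropped)
  }
  out <- summarise(S, P)
  if (split_by_post_p) {
    for (sgn in c(1, -1)) {
      sel <- post_sign == sgn
      out[[if (sgn > 0) "pos" else "neg"]] <-
        if (any(sel)) summarise(S[sel, , drop = FALSE], P[sel, , drop = FALSE]) else NULL
    }
  }
  out
}

#' Turn rate and mean turn angle by bearing
#'
#' Bins all samples by bearing to the source and reports, per bin, the rate
#' of large-turn events (events per second, one step being one second for
#' the discrete agent) and the mean magnitude of those events. Bins with no
#' occupancy are reported as `NA`, not zero.
#'
#' @param trajectories list of trajectories.
#' @param source `c(x, y)` (mm).
#' @param bin_width bearing bin width (degrees, default 30).
#' @param large_threshold degrees (default 30).
#' @return data frame `mid`, `occupancy_s`, `n_turns`, `turn_rate`
#'   (events/s), `mean_turn_deg`.
#' @export
turn_stats_by_bearing <- function(trajectories, source, bin_width = 30,
                                  large_threshold = 30) {
  breaks <- seq(-180, 180, by = bin_width)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  occ <- rep(0, length(mids)); n_turn <- rep(0, length(mids))
  sum_mag <- rep(0, length(mids))
  for (tr in trajectories) {
    b <- bearing_to_source(tr, source)
    dt <- stats::median(diff(tr$t))
    bin <- findInterval(b, breaks, left.open = TRUE, all.inside = TRUE)
    tab <- table(factor(bin, levels = seq_along(mids)))
    occ <- occ + as.vector(tab) * dt
    ev <- detect_turns(tr, large_threshold = large_threshold, source = source)
    ev <- ev[ev$is_large & !is.na(ev$bearing_deg), , drop = FALSE]
    if (nrow(ev) > 0) {
      eb <- findInterval(ev$bearing_deg, breaks, left.open = TRUE, all.inside = TRUE)
      for (j in seq_len(nrow(ev))) {
        n_turn[eb[j]] <- n_turn[eb[j]] + 1
        sum_mag[eb[j]] <- sum_mag[eb[j]] + ev$magnitude_deg[j]
      }
    }
  }
  data.frame(mid = mids, occupancy_s = occ, n_turns = n_turn,
             turn_rate = ifelse(occ > 0, n_turn / occ, NA_real_),
             mean_turn_deg = ifelse(n_turn > 0, sum_mag / n_turn, NA_real_))
}
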