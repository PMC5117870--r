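#' Multi-point larval track
#'
#' Per-frame tail, centroid and head coordinates of a tracked larva, as
#' produced by video tracking: the raw material for the body-bend,
#' angular-velocity and tail-speed channels. Stored as a data frame with
#' columns `frame`, `tail_x`, `tail_y`, `mid_x`, `mid_y`, `head_x`,
#' `head_y`, plus a frame rate and an identifier as attributes.
#'
#' @param df data frame with the seven columns above (mm coordinates).
#' @param fps frame rate (Hz, > 0).
#' @param id track identifier.
#' @return object of class `larva_track`.
#' @export
larva_track <- function(df, fps, id = "track") {
  need <- c("frame", "tail_x", "tail_y", "mid_x", "mid_y", "head_x", "head_y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("track is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  stopifnot_scalar(fps)
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (any(!is.finite(as.matrix(df[, setdiff(need, "frame")]))))
    stop("track coordinates must be finite", call. = FALSE)
  structure(df[, need], fps = fps, id = id,
            class = c("larva_track", "data.frame"))
}

#' Read / write a larval track
#'
#' Tracks are stored as a CSV of the per-frame coordinates plus a JSON
#' sidecar (`<path>.json`) carrying the frame rate and identifier. Isolated
#' single-frame gaps (NA) are linearly interpolated on read and flagged;
#' longer NA runs are a format error.
#'
#' @param path CSV path.
#' @return a `larva_track` (with attribute `interpolated_frames` when gaps
#'   were filled); `write_track` returns `path` invisibly.
#' @export
read_track <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("track sidecar ", side, " not found", call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  need <- c("frame", "tail_x", "tail_y", "mid_x", "mid_y", "head_x", "head_y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("track file is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  filled <- integer(0)
  for (col in setdiff(need, "frame")) {
    v <- df[[col]]
    if (anyNA(v)) {
      r <- rle(is.na(v))
      if (any(r$lengths[r$values] > 1L))
        stop("NA run longer than one frame in column ", col, call. = FALSE)
      filled <- union(filled, which(is.na(v)))
      df[[col]] <- stats::approx(seq_along(v), v, xout = seq_along(v), rule = 2)$y
    }
  }
  tr <- larva_track(df, fps = as.numeric(meta$fps),
                    id = meta$id %||% "track")
  attr(tr, "interpolated_frames") <- filled
  tr
}

#' @rdname read_track
#' @param track a `larva_track`.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "larva_track"))
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  jsonlite::write_json(list(fps = attr(track, "fps"), id = attr(track, "id"),
                            units = "mm"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# signed angle (deg, CCW/left-positive) of vector (x, y) in math convention
vec_angle_deg <- function(x, y) rad2deg(atan2(y, x))

#' Derive kinematic channels from a track
#'
#' Computes the three channels used to characterise larval crawling:
#' \describe{
#'   \item{body bend}{signed angle between the tail-to-centroid axis and the
#'     centroid-to-head axis (degrees, left-positive: positive when the head
#'     points left of the body axis).}
#'   \item{anterior angular velocity}{time derivative of the
#'     centroid-to-head axis orientation (degrees/s), computed by central
#'     differences on the unwrapped orientation, edge frames one-sided. No
#'     smoothing is applied by default.}
#'   \item{tail speed}{magnitude of the tail displacement per frame times
#'     the frame rate (mm/s), central differences, edge-padded.}
#' }
#' Frames where the tail-centroid or centroid-head axis has zero length are
#' flagged invalid (`valid` column FALSE; their angular quantities are NA).
#'
#' @param track a `larva_track`.
#' @return data frame with columns `t` (s), `body_bend_deg`,
#'   `ang_vel_deg_s`, `tail_speed_mm_s`, `valid`; class `derived_channels`,
#'   frame rate kept as attribute.
#' @export
derive_channels <- function(track) {
  stopifnot(inherits(track, "larva_track"))
  fps <- attr(track, "fps")
  n <- nrow(track)
  bx <- track$mid_x - track$tail_x; by <- track$mid_y - track$tail_y
  hx <- track$head_x - track$mid_x; hy <- track$head_y - track$mid_y
  valid <- (bx^2 + by^2 > 0) & (hx^2 + hy^2 > 0)
  body_axis <- vec_angle_deg(bx, by)
  head_axis <- vec_angle_deg(hx, hy)
  bend <- wrap_deg(head_axis - body_axis)
  bend[!valid] <- NA_real_
  # unwrap the head-axis orientation before differencing
  hu <- head_axis
  if (n > 1) {
    d <- wrap_deg(diff(head_axis))
    hu <- cumsum(c(head_axis[1], d))
  }
  cdiff <- function(v) {
    if (length(v) < 2) return(rep(NA_real_, length(v)))
    c(v[2] - v[1], (v[-(1:2)] - v[-((length(v) - 1):length(v))]) / 2,
      v[length(v)] - v[length(v) - 1])
  }
  ang_vel <- cdiff(hu) * fps
  ang_vel[!valid] <- NA_real_
  tail_speed <- sqrt(cdiff(track$tail_x)^2 + cdiff(track$tail_y)^2) * fps
  structure(data.frame(t = (track$frame - track$frame[1]) / fps,
                       body_bend_deg = bend, ang_vel_deg_s = ang_vel,
                       tail_speed_mm_s = tail_speed, valid = valid),
            fps = fps, class = c("derived_channels", "data.frame"))
}

#' Segment head sweeps from the angular-velocity channel
#'
#' A head sweep is the period between two successive zero crossings of the
#' anterior-body angular speed. Each sweep is summarised by its onset,
#' offset, duration, peak angular speed and mean tail speed, and classified
#' by the tail-speed cuts: `stop` if the sweep-average tail speed is below
#' `stop_cut` mm/s, `crawl` if above `crawl_cut`, otherwise `intermediate`.
#'
#' @param channels a `derived_channels` data frame.
#' @param stop_cut,crawl_cut tail-speed class cuts (mm/s; defaults 0.3 and
#'   0.7).
#' @return data frame, one row per sweep: `onset_t`, `offset_t`,
#'   `duration_s`, `peak_ang_speed_deg_s`, `mean_tail_speed_mm_s`,
#'   `direction` (+1 left, -1 right), `class`. Empty when the channel has
#'   fewer than two zero crossings.
#' @export
segment_head_sweeps <- function(channels, stop_cut = 0.3, crawl_cut = 0.7) {
  v <- channels$ang_vel_deg_s
  t <- channels$t
  ok <- !is.na(v)
  cross <- which(ok[-1] & ok[-length(v)] & v[-1] * v[-length(v)] <= 0 & v[-length(v)] != 0)
  if (length(cross) < 2)
    return(data.frame(onset_t = numeric(), offset_t = numeric(),
                      duration_s = numeric(), peak_ang_speed_deg_s = numeric(),
                      mean_tail_speed_mm_s = numeric(), direction = numeric(),
                      class = character()))
  out <- lapply(seq_len(length(cross) - 1L), function(i) {
    a <- cross[i] + 1L; b <- cross[i + 1L]
    seg <- a:b
    ts <- mean(channels$tail_speed_mm_s[seg], na.rm = TRUE)
    data.frame(onset_t = t[a], offset_t = t[b], duration_s = t[b] - t[a],
               peak_ang_speed_deg_s = max(abs(v[seg]), na.rm = TRUE),
               mean_tail_speed_mm_s = ts,
               direction = sign(mean(v[seg], na.rm = TRUE)),
               class = if (ts < stop_cut) "stop" else if (ts > crawl_cut) "crawl" else "intermediate")
  })
  do.call(rbind, out)
}

#' Detect peristalsis-inhibition events
#'
#' Finds local minima of the (optionally smoothed) tail-speed channel that
#' fall below a threshold — moments when forward crawling pauses. Events
#' can be used as alignment anchors for event-triggered averaging.
#'
#' @param channels a `derived_channels` data frame.
#' @param threshold tail speed below which a minimum counts (mm/s, default
#'   0.3). A threshold of 0 yields no events.
#' @param smooth_frames width of the running-mean smoother (frames, odd;
#'   default 5; 1 disables smoothing).
#' @param min_separation_s minimum spacing between events (s).
#' @return numeric vector of event times (s).
#' @export
detect_peristalsis_inhibition <- function(channels, threshold = 0.3,
                                          smooth_frames = 5,
                                          min_separation_s = 0.5) {
  v <- channels$tail_speed_mm_s
  if (smooth_frames > 1) {
    k <- rep(1 / smooth_frames, smooth_frames)
    v <- stats::filter(v, k, sides = 2)
    v <- as.numeric(v)
    # edges: keep raw values where the filter is undefined
    v[is.na(v)] <- channels$tail_speed_mm_s[is.na(v)]
  }
  n <- length(v)
  if (n < 3) return(numeric(0))
  is_min <- c(FALSE, v[2:(n - 1)] <= v[1:(n - 2)] & v[2:(n - 1)] <= v[3:n], FALSE)
  cand <- which(is_min & v < threshold)
  if (length(cand) == 0) return(numeric(0))
  times <- channels$t[cand]
  keep <- c(TRUE, diff(times) >= min_separation_s)
  # collapse plateaus / near-duplicates
  times[keep]
}

#' Synthesize a kinematically consistent larval track
#'
#' Generates a three-point (tail, centroid, head) track emulating the two
#' decoupled rhythms of larval crawling: a peristaltic speed rhythm
#' (default 1.0 Hz) on the centroid's forward progress and a slower lateral
#' oscillation of the head axis (default 0.3 Hz). An optional stop schedule
#' inserts peristalsis-inhibition phases during which forward speed drops
#' to near zero while the lateral oscillation continues. Derived channels
#' of the result recover the generator's frequencies and amplitudes, which
#' is what makes the analysis suite testable without recorded data.
#'
#' @param fps frame rate (Hz, default 7).
#' @param duration track length (s, default 60).
#' @param peristalsis_hz peristaltic rhythm (Hz, default 1.0).
#' @param lateral_hz lateral head-oscillation rhythm (Hz, default 0.3).
#' @param sweep_amplitude_deg half-amplitude of the head-axis oscillation
#'   (degrees, < 180; default 30).
#' @param crawl_speed_mm_s mean forward speed while crawling (default 1).
#' @param speed_mod relative depth of the peristaltic speed modulation in
#'   (0, 1] (default 0.8).
#' @param stops optional data frame with columns `start`, `duration` (s):
#'   scheduled peristalsis-inhibition phases.
#' @param path_turn_deg_s slow steady curvature of the base path
#'   (degrees/s, default 2).
#' @param body_len_mm tail-to-centroid and centroid-to-head axis lengths
#'   (default 1.5 mm each).
#' @param noise_mm coordinate jitter std (mm, default 0).
#' @param seed RNG seed.
#' @return a `larva_track`; the generator spec is attached as attribute
#'   `spec`.
#' @export
synthesize_track <- function(fps = 7, duration = 60, peristalsis_hz = 1.0,
                             lateral_hz = 0.3, sweep_amplitude_deg = 30,
                             crawl_speed_mm_s = 1, speed_mod = 0.8,
                             stops = NULL, path_turn_deg_s = 2,
                             body_len_mm = 1.5, noise_mm = 0, seed = 1L) {
  if (sweep_amplitude_deg >= 180)
    stop("sweep_amplitude_deg must be < 180", call. = FALSE)
  if (speed_mod <= 0 || speed_mod > 1)
    stop("speed_mod must lie in (0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  n <- floor(duration * fps) + 1L
  t <- (seq_len(n) - 1) / fps
  # forward speed: peristaltic modulation, gated by the stop schedule
  speed <- crawl_speed_mm_s * (1 + speed_mod * sin(2 * pi * peristalsis_hz * t))
  if (!is.null(stops)) {
    for (i in seq_len(nrow(stops))) {
      in_stop <- t >= stops$start[i] & t < stops$start[i] + stops$duration[i]
      speed[in_stop] <- speed[in_stop] * 0.02
    }
  }
  psi <- deg2rad(path_turn_deg_s) * t          # slowly curving body axis
  # centroid integrates the forward speed along the body axis
  dx <- speed * cos(psi) / fps
  dy <- speed * sin(psi) / fps
  cx <- cumsum(c(0, dx[-n])); cy <- cumsum(c(0, dy[-n]))
  # head axis = body axis + lateral oscillation
  phi <- deg2rad(sweep_amplitude_deg) * sin(2 * pi * lateral_hz * t)
  ha <- psi + phi
  df <- data.frame(frame = seq_len(n) - 1L,
                   tail_x = cx - body_len_mm * cos(psi),
                   tail_y = cy - body_len_mm * sin(psi),
                   mid_x = cx, mid_y = cy,
                   head_x = cx + body_len_mm * cos(ha),
                   head_y = cy + body_len_mm * sin(ha))
  if (noise_mm > 0)
    for (col in names(df)[-1]) df[[col]] <- df[[col]] + stats::rnorm(n, 0, noise_mm)
  tr <- larva_track(df, fps = fps, id = sprintf("synthetic-%d", as.integer(seed)))
  attr(tr, "spec") <- list(fps = fps, duration = duration,
                           peristalsis_hz = peristalsis_hz, lateral_hz = lateral_hz,
                           sweep_amplitude_deg = sweep_amplitude_deg,
                           crawl_speed_mm_s = crawl_speed_mm_s,
                           speed_mod = speed_mod, stops = stops,
                           path_turn_deg_s = path_turn_deg_s,
                           body_len_mm = body_len_mm, noise_mm = noise_mm,
                           seed = as.integer(seed))
  tr
}

#' Amplitude spectrum of a derived channel
#'
#' Raw DFT magnitude of a (demeaned) channel, for checking the rhythms of a
#' track. Frames flagged invalid are linearly interpolated first.
#'
#' @param channels a `derived_channels` data frame.
#' @param channel `"ang_vel_deg_s"` or `"tail_speed_mm_s"`.
#' @return data frame `frequency` (Hz), `amplitude`.
#' @export
channel_spectrum <- function(channels, channel = c("ang_vel_deg_s", "tail_speed_mm_s")) {
  channel <- match.arg(channel)
  fps <- attr(channels, "fps")
  v <- channels[[channel]]
  if (anyNA(v)) v <- stats::approx(seq_along(v), v, xout = seq_along(v), rule = 2)$y
  v <- v - mean(v)
  n <- length(v)
  nf <- n %/% 2L
  data.frame(frequency = (seq_len(nf) - 1) * fps / n,
             amplitude = (Mod(stats::fft(v)) / n)[seq_len(nf)])
}
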