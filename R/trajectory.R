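#' Trajectory container
#'
#' A uniformly sampled time series of agent state: position, heading, sensed
#' concentration and per-step (or per-sample) turn signal, plus provenance
#' (configuration and seed) kept as attributes. Built on a plain data frame
#' so all the usual verbs apply.
#'
#' Columns common to both agents: `t` (s), `x`, `y` (mm), `theta` (heading).
#' The discrete agent adds `s` (sensed concentration), `p` (one-step change),
#' `turn` (signed applied re-orientation, post-limit, pre-noise, radians).
#' The continuous agent adds `theta_dot`, `B` (bearing), firing rates
#' `EL`, `ER`, `CL`, `CR`, input `A` and sensed `C`.
#'
#' @param df data frame of samples.
#' @param config list used to produce it.
#' @param seed RNG seed, if any.
#' @param model `"discrete"` or `"cpg"`.
#' @return object of class `c("taxis_trajectory", "data.frame")`.
#' @export
taxis_trajectory <- function(df, config = list(), seed = NA_integer_, model = "discrete") {
  stopifnot(is.data.frame(df))
  structure(df, config = config, seed = seed, model = model,
            class = c("taxis_trajectory", "data.frame"))
}

#' @export
print.taxis_trajectory <- function(x, ...) {
  cat(sprintf("<taxis_trajectory: %s model, %d samples>\n",
              attr(x, "model"), nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Write / read a trajectory as CSV plus JSON metadata
#'
#' The CSV holds the sample table (angles converted to degrees in columns
#' suffixed `_deg`); the `<path>.json` sidecar records model, seed and
#' configuration so a run can be reproduced.
#'
#' @param traj a `taxis_trajectory`.
#' @param path CSV output path.
#' @return `path`, invisibly; `read_trajectory` returns the trajectory.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  for (col in intersect(c("theta", "B", "turn"), names(df))) {
    df[[paste0(col, "_deg")]] <- if (attr(traj, "model") == "cpg" && col %in% c("theta", "B"))
      df[[col]] else rad2deg(df[[col]])
    df[[col]] <- NULL
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(model = attr(traj, "model"), seed = attr(traj, "seed"),
                            config = attr(traj, "config")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE) else list(model = "discrete")
  for (col in intersect(c("theta_deg", "B_deg", "turn_deg"), names(df))) {
    bare <- sub("_deg$", "", col)
    df[[bare]] <- if (identical(meta$model, "cpg") && bare %in% c("theta", "B"))
      df[[col]] else deg2rad(df[[col]])
    df[[col]] <- NULL
  }
  taxis_trajectory(df, config = meta$config,
                   seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
                   model = meta$model)
}
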