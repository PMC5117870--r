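#' Read and validate a run configuration
#'
#' Run configurations are YAML (or JSON) files selecting a model
#' (`discrete` or `cpg`), its parameters (degree/mm/second units, matching
#' the constructors' arguments), a field specification, ensemble size and
#' seed, and optional analysis requests. Unknown keys produce warnings (so
#' configs stay forward-compatible), violations are errors listed with
#' their field paths.
#'
#' @param path configuration file.
#' @return `read_run_config`: the validated config as a list with defaults
#'   filled in. `validate_run_config`: character vector of violations
#'   (empty when the config is valid).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  issues <- validate_run_config(cfg)
  if (length(issues) > 0)
    stop("invalid config:\n  ", paste(issues, collapse = "\n  "), call. = FALSE)
  fill_config_defaults(cfg)
}

#' @rdname read_run_config
#' @param config a config list (as parsed from YAML) or a file path.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  issues <- character(0)
  known_top <- c("model", "agent", "field", "ensemble", "analyses", "output")
  extra <- setdiff(names(config), known_top)
  if (length(extra) > 0)
    warning("unknown config key(s) ignored: ", paste(extra, collapse = ", "),
            call. = FALSE)
  if (is.null(config$model) || !config$model %in% c("discrete", "cpg"))
    issues <- c(issues, "model: must be 'discrete' or 'cpg'")
  fs <- config$field
  if (!is.null(fs)) {
    if (identical(fs$type, "gaussian")) {
      if (!is.null(fs$sigma_x) && fs$sigma_x <= 0) issues <- c(issues, "field.sigma_x: must be > 0")
      if (!is.null(fs$sigma_y) && fs$sigma_y <= 0) issues <- c(issues, "field.sigma_y: must be > 0")
      if (!is.null(fs$rho) && abs(fs$rho) >= 1) issues <- c(issues, "field.rho: must lie in (-1, 1)")
      if (!is.null(fs$c) && fs$c < 0) issues <- c(issues, "field.c: must be >= 0")
    } else if (identical(fs$type, "grid")) {
      if (is.null(fs$path)) issues <- c(issues, "field.path: required for grid fields")
    } else issues <- c(issues, "field.type: must be 'gaussian' or 'grid'")
  }
  ag <- config$agent
  if (!is.null(ag)) {
    if (!is.null(ag$lambda_step) && ag$lambda_step <= 0)
      issues <- c(issues, "agent.lambda_step: must be > 0")
    if (!is.null(ag$noise_sigma) && ag$noise_sigma < 0)
      issues <- c(issues, "agent.noise_sigma: must be >= 0")
    if (!is.null(ag$tau) && ag$tau <= 0) issues <- c(issues, "agent.tau: must be > 0")
  }
  en <- config$ensemble
  if (!is.null(en)) {
    if (!is.null(en$n_agents) && en$n_agents < 1)
      issues <- c(issues, "ensemble.n_agents: must be >= 1")
    if (is.null(en$seed)) issues <- c(issues, "ensemble.seed: every stochastic run carries an explicit seed")
  }
  issues
}

fill_config_defaults <- function(cfg) {
  cfg$ensemble <- utils::modifyList(list(n_agents = 1L, seed = 1L),
                                    cfg$ensemble %||% list())
  cfg$field <- cfg$field %||% list(type = "gaussian")
  if (identical(cfg$field$type, "gaussian"))
    cfg$field <- utils::modifyList(
      list(type = "gaussian", mu_x = 50, mu_y = 50, sigma_x = 10, sigma_y = 10,
           rho = 0, c = 1e3, xlim = c(0, 100), ylim = c(0, 100)), cfg$field)
  cfg$agent <- cfg$agent %||% list()
  cfg
}

config_field <- function(cfg) {
  fs <- cfg$field
  if (identical(fs$type, "grid")) return(read_grid_field(fs$path))
  gaussian_field(fs$mu_x, fs$mu_y, fs$sigma_x, fs$sigma_y, rho = fs$rho,
                 c = fs$c, xlim = unlist(fs$xlim), ylim = unlist(fs$ylim))
}

#' Run a configured experiment
#'
#' Simulates the configured ensemble, runs any requested analyses and
#' writes everything under `out_dir` together with a manifest (config,
#' seeds, package version, file hashes) from which the run can be
#' reproduced exactly.
#'
#' Supported analysis requests (entries of `analyses` in the config):
#' `bearings` (bearing-to-source histogram; fields `bins`),
#' `spectrum` (heading-velocity spectrum), `turns` (turn events),
#' `pi` (preference index; field `midline`), `prc` (CPG only; fields
#' `amplitudes`, `n_points`).
#'
#' @param config a config list from [read_run_config()] or a path.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  field <- config_field(config)
  n <- config$ensemble$n_agents
  seed <- config$ensemble$seed
  files <- character(0)

  if (identical(config$model, "discrete")) {
    ag <- config$agent
    cfg <- discrete_config(theta_b = ag$theta_b %||% 10, g = ag$g %||% 0,
                           s_t = ag$s_t %||% 0, lambda_step = ag$lambda_step %||% 1,
                           noise_sigma = ag$noise_sigma %||% 0,
                           n_steps = ag$n_steps %||% 800, seed = seed)
    trajs <- simulate_discrete_ensemble(cfg, field, n_agents = n)
  } else {
    ag <- config$agent
    params <- cpg_params(g_sens = ag$g_sens %||% 0,
                         b_t = ag$b_t %||% 19, tau = ag$tau %||% 0.1,
                         zeta = ag$zeta %||% 0.5, k = ag$k %||% 1)
    starts <- ag$starts %||% list(list(x = 0, y = 0))
    trajs <- lapply(seq_len(max(n, length(starts))), function(i) {
      st <- starts[[((i - 1) %% length(starts)) + 1]]
      simulate_cpg(params, field, duration = ag$duration %||% 200,
                   init = cpg_initial_state(x = st$x, y = st$y))
    })
  }
  for (i in seq_along(trajs)) {
    f <- file.path(out_dir, sprintf("traj_%03d.csv", i))
    write_trajectory(trajs[[i]], f)
    files <- c(files, f)
  }

  src <- c(config$field$mu_x %||% 0, config$field$mu_y %||% 0)
  for (an in config$analyses %||% list()) {
    kind <- if (is.list(an)) an$kind else an
    f <- file.path(out_dir, paste0(kind, ".csv"))
    res <- switch(kind,
      bearings = bearing_distribution(trajs, src, bins = (if (is.list(an)) an$bins else NULL) %||% 36),
      spectrum = {
        sp <- heading_speed_spectrum(trajs, dt = stats::median(diff(trajs[[1]]$t)))
        data.frame(frequency = sp$frequency, mean_amplitude = sp$mean_amplitude)
      },
      turns = do.call(rbind, lapply(trajs, detect_turns, source = src)),
      pi = data.frame(preference_index = preference_index(
        trajs, src, midline = (if (is.list(an)) an$midline else NULL) %||% 50)),
      prc = {
        pars <- cpg_params(b_t = config$agent$b_t %||% 19)
        phase_response_curve(pars,
          amplitudes = unlist((if (is.list(an)) an$amplitudes else NULL) %||% c(-4, 4)),
          n_points = (if (is.list(an)) an$n_points else NULL) %||% 102)
      },
      stop("unknown analysis kind: ", kind, call. = FALSE))
    utils::write.csv(res, f, row.names = FALSE)
    files <- c(files, f)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("oscillotaxis")),
    config = config, master_seed = seed,
    agent_seeds = if (identical(config$model, "discrete")) split_seeds(seed, n + 1L) else NULL,
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
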