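#' Default run configuration
#'
#' A full, validated configuration for reproducible runs: model parameters,
#' solver settings, analysis (peak/classification) settings, the supply-level
#' scan, and the stability reduction. [read_run_config()] merges a JSON or
#' YAML file over these defaults, rejecting unknown keys.
#'
#' @return A nested list of class `"run_config"`.
#' @export
default_run_config <- function() {
  structure(list(
    model = unclass(signaling_params()),
    solver = unclass(solver_settings(t_end = 2000)),
    analysis = list(variable = "x", window = c(50, 1000),
                    min_height_frac = 0.05, min_peaks = 10,
                    persistence_ratio = 0.25),
    scan = list(p_values = NULL, eps_min = 0.01, eps_max = 0.25,
                points = 13, p_c = NULL),
    stability = list(p_c = 0.8, order = c(2, 1), alt_order = c(3, 1),
                     eps_hi = 0.25, grid_points = 80)
  ), class = "run_config")
}

.check_keys <- function(given, allowed, where) {
  unknown <- setdiff(names(given), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
}

#' Validate a run configuration
#'
#' @param config A nested list following the [default_run_config()] layout.
#' @return The validated `"run_config"` (sections completed with defaults).
#' @export
validate_run_config <- function(config) {
  defaults <- default_run_config()
  .check_keys(config, names(defaults), "config")
  for (section in names(config)) {
    if (!is.null(config[[section]]) && !is.list(config[[section]])) {
      stop(sprintf("config section `%s` must be a mapping", section),
           call. = FALSE)
    }
    .check_keys(config[[section]], names(defaults[[section]]),
                sprintf("config$%s", section))
  }
  merged <- defaults
  for (section in names(config)) {
    for (key in names(config[[section]])) {
      merged[[section]][[key]] <- config[[section]][[key]]
    }
  }
  validate_params(merged$model)
  do.call(solver_settings, merged$solver)
  stopifnot(length(merged$analysis$window) == 2L,
            merged$analysis$variable %in% c("x", "z"),
            length(merged$stability$order) == 2L)
  merged
}

#' Read a run configuration from JSON or YAML
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file whose top level
#'   follows the [default_run_config()] layout. Omitted sections and keys
#'   take their defaults; unknown keys are an error.
#' @return A validated `"run_config"` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml, got .", ext, call. = FALSE))
  if (!is.list(raw)) stop("config top level must be a mapping", call. = FALSE)
  validate_run_config(raw)
}

.config_payload <- function(config) {
  cfg <- unclass(config)
  cfg$scan$p_values <- if (is.null(cfg$scan$p_values)) NULL else cfg$scan$p_values
  cfg
}

#' Run one simulation and write its outputs
#'
#' Integrates the configured model (optionally at an overridden supply
#' level), writes the trajectory CSV (+ JSON sidecar) and a summary JSON
#' embedding the resolved configuration.
#'
#' @param config A `"run_config"` (see [default_run_config()]).
#' @param p Optional supply-level override.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the trajectory, the summary row, and the
#'   output paths.
#' @export
run_simulate <- function(config = default_run_config(), p = NULL,
                         out_dir = ".") {
  config <- validate_run_config(config)
  params <- validate_params(config$model)
  if (!is.null(p)) params <- set_p(params, p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  settings <- do.call(solver_settings, config$solver)
  traj <- simulate_fluctuations(params, settings = settings)
  an <- config$analysis
  sm <- summarize_oscillation(traj, variable = an$variable,
                              window = an$window,
                              min_height_frac = an$min_height_frac,
                              min_peaks = an$min_peaks,
                              persistence_ratio = an$persistence_ratio)
  traj_path <- file.path(out_dir, "trajectory.csv")
  write_trajectory(traj, traj_path)
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(summary = as.list(sm),
                            config = .config_payload(config),
                            p = params$p),
                       summary_path, auto_unbox = TRUE, digits = NA)
  invisible(list(trajectory = traj, summary = sm,
                 paths = c(trajectory = traj_path, summary = summary_path)))
}

#' Run the supply-level scan and the log-scaling fits
#'
#' Builds the `p` grid (an explicit `scan$p_values`, or `p_c + eps` over the
#' configured `eps` range), runs [scan_p()], writes the scan CSV, and — when
#' at least three valid positive-`eps` rows exist — fits frequency and mean
#' amplitude against `ln(eps)`, writing one JSON per fit.
#'
#' @inheritParams run_simulate
#' @return Invisibly, a list with the scan tibble, the fits (possibly
#'   `NULL`), and output paths.
#' @export
run_scan <- function(config = default_run_config(), out_dir = ".") {
  config <- validate_run_config(config)
  params <- validate_params(config$model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  settings <- do.call(solver_settings, config$solver)
  sc <- config$scan
  p_c <- sc$p_c
  if (is.null(p_c)) p_c <- critical_p_linear(params)
  p_values <- sc$p_values
  if (is.null(p_values)) {
    p_values <- p_c + seq(sc$eps_min, sc$eps_max, length.out = sc$points)
  }
  an <- config$analysis
  scan <- scan_p(params, p_values, settings = settings, p_c = p_c,
                 variable = an$variable, window = an$window,
                 min_height_frac = an$min_height_frac,
                 min_peaks = an$min_peaks,
                 persistence_ratio = an$persistence_ratio)
  scan_path <- file.path(out_dir, "scan.csv")
  utils::write.csv(scan, scan_path, row.names = FALSE)
  paths <- c(scan = scan_path)
  fits <- list(frequency = NULL, mean_amplitude = NULL)
  usable <- scan$ok & !is.na(scan$eps) & scan$eps > 0
  if (sum(usable) >= 3L) {
    for (metric in c("frequency", "mean_amplitude")) {
      fit <- fit_log(scan$eps[usable], scan[[metric]][usable])
      fit_path <- file.path(out_dir, sprintf("logfit_%s.json", metric))
      write_log_fit(fit, fit_path)
      fits[[metric]] <- fit
      paths[paste0("fit_", metric)] <- fit_path
    }
  } else {
    warning("fewer than 3 valid scan points with eps > 0; log fits skipped",
            call. = FALSE)
  }
  jsonlite::write_json(list(p_c = p_c, config = .config_payload(config)),
                       file.path(out_dir, "scan_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(scan = scan, fits = fits, p_c = p_c, paths = paths))
}

#' Locate the critical supply level
#'
#' @inheritParams run_simulate
#' @param bracket Bracket for both the determinant root and the simulation
#'   bisection.
#' @param method `"linear"` (determinant root), `"sim"` (trajectory
#'   bisection) or `"both"`.
#' @param out_dir Optional output directory; when given, writes
#'   `critical.json`.
#' @return A list with the requested estimates (`p_c_linear`, `p_c_sim`).
#' @export
run_critical <- function(config = default_run_config(),
                         bracket = c(0.795, 0.81),
                         method = c("both", "sim", "linear"),
                         out_dir = NULL) {
  config <- validate_run_config(config)
  method <- match.arg(method)
  params <- validate_params(config$model)
  settings <- do.call(solver_settings, config$solver)
  an <- config$analysis
  out <- list(p_c_linear = NULL, p_c_sim = NULL)
  if (method %in% c("both", "linear")) {
    out$p_c_linear <- critical_p_linear(params)
  }
  if (method %in% c("both", "sim")) {
    out$p_c_sim <- find_critical_p_sim(params, bracket = bracket,
                                       settings = settings,
                                       variable = an$variable,
                                       window = an$window)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(c(out, list(config = .config_payload(config))),
                         file.path(out_dir, "critical.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run the full stability reduction and bifurcation analysis
#'
#' Performs the eigenvector reduction at the configured `p_c` at both the
#' default and the alternative elimination order, searches the nonzero-root
#' count of the reduced fixed-point equation for a change first on
#' `(0, eps_hi]` and, if the count is constant there, on `[-eps_hi, 0)`
#' (for the published constants the nonzero branch pair is born below
#' criticality; see the methods vignette). Writes the reduced model, the
#' bifurcation JSON, and a diagram CSV.
#'
#' @inheritParams run_simulate
#' @return Invisibly, a list: `model` (default order), `bifurcation`,
#'   `eps_star` (signed), `eps_star_alt_order`, `searched_below` (logical),
#'   and output paths.
#' @export
run_stability <- function(config = default_run_config(), out_dir = ".") {
  config <- validate_run_config(config)
  params <- validate_params(config$model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stability
  reduce_at <- function(order) {
    reduce_slow_mode(eliminate_fast_mode(params, p_c = st$p_c, order = order))
  }
  threshold <- function(model) {
    res <- tryCatch(
      list(bif = bifurcation_threshold(model, 0, st$eps_hi,
                                       grid_points = st$grid_points),
           below = FALSE),
      error = function(err) {
        bif <- find_bifurcation(model, eps_max = st$eps_hi)
        list(bif = bif, below = identical(bif$side, "below"))
      })
    res
  }
  model <- reduce_at(st$order)
  res <- threshold(model)
  model_alt <- reduce_at(st$alt_order)
  res_alt <- threshold(model_alt)
  paths <- c(model = file.path(out_dir, "reduced_model.json"),
             bifurcation = file.path(out_dir, "bifurcation.json"),
             diagram = file.path(out_dir, "diagram.csv"))
  write_reduced_model(model, paths["model"])
  write_bifurcation(res$bif, paths["bifurcation"])
  write_bifurcation_diagram(res$bif, paths["diagram"])
  jsonlite::write_json(list(
    eps_star = res$bif$eps_star,
    searched_below_criticality = res$below,
    eps_star_alt_order = res_alt$bif$eps_star,
    alt_order = st$alt_order,
    config = .config_payload(config)
  ), file.path(out_dir, "stability.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(model = model, bifurcation = res$bif,
                 eps_star = res$bif$eps_star,
                 searched_below = res$below,
                 eps_star_alt_order = res_alt$bif$eps_star,
                 paths = paths))
}
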