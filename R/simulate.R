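#' Integration and sampling settings
#'
#' Settings for the long-horizon integration of the fluctuation kinetics.
#' The defaults mirror the published protocol (horizon `t = 30000`) but with
#' integration tolerances tightened well below the fluctuation magnitudes
#' (~1e-6 to 1e-3), so that trajectory features are solver-converged; see the
#' methods vignette. Output sampling is decoupled from the internal adaptive
#' stepping.
#'
#' @param t_end Final time (> 0). Analyses of the standard window
#'   `t in [50, 1000]` only need `t_end = 2000`.
#' @param sample_dt Output grid spacing (> 0); `0.1` keeps peak counting
#'   stable.
#' @param rel_tol,abs_tol Relative and absolute integration tolerances, each
#'   in `(0, 1e-2]`.
#' @param max_steps Internal step-count guard per output interval.
#' @return A list of class `"solver_settings"`.
#' @export
solver_settings <- function(t_end = 30000, sample_dt = 0.1,
                            rel_tol = 1e-8, abs_tol = 1e-10,
                            max_steps = 50000) {
  stopifnot(is.numeric(t_end), length(t_end) == 1L, is.finite(t_end), t_end > 0,
            is.numeric(sample_dt), sample_dt > 0)
  for (tol in c(rel_tol, abs_tol)) {
    if (!is.numeric(tol) || tol <= 0 || tol > 1e-2) {
      stop("integration tolerances must lie in (0, 1e-2]", call. = FALSE)
    }
  }
  structure(list(t_end = t_end, sample_dt = sample_dt, rel_tol = rel_tol,
                 abs_tol = abs_tol, max_steps = max_steps),
            class = "solver_settings")
}

#' Integrate the fluctuation kinetics
#'
#' Integrates the two-variable fluctuation ODE system with an adaptive,
#' stiffness-switching solver ([deSolve::lsoda()]) and samples the solution
#' on a uniform grid. The system is fully deterministic; identical inputs
#' give identical trajectories.
#'
#' @param params A `"signaling_params"` object.
#' @param init Initial fluctuations `c(x, z)`; the published protocol seeds
#'   both at `1e-6`.
#' @param settings A [solver_settings()] list.
#' @return A tibble of class `"fluct_traj"` with columns `t`, `x`, `z`,
#'   `X_total = X_s + x`, `Z_total = Z_s + z`, and attributes `params`, `ss`,
#'   `init`, `settings`.
#' @examples
#' \donttest{
#' traj <- simulate_fluctuations(signaling_params(p = 1.0),
#'                               settings = solver_settings(t_end = 2000))
#' }
#' @export
simulate_fluctuations <- function(params,
                                  init = c(x = 1e-6, z = 1e-6),
                                  settings = solver_settings()) {
  params <- validate_params(params)
  if (length(init) != 2L || !is.numeric(init) || any(!is.finite(init))) {
    stop("`init` must be two finite numbers (x0, z0)", call. = FALSE)
  }
  init <- stats::setNames(as.numeric(init), c("x", "z"))
  ss <- steady_state(params)
  cf <- field_coefficients(params, ss)
  cx <- cf["x", ]
  cz <- cf["z", ]
  rhs <- function(t, y, parms) {
    x <- y[1L]
    z <- y[2L]
    m1 <- x * x
    m2 <- x * z
    m3 <- z * z
    list(c(cx[1L] * x + cx[2L] * z + cx[3L] * m1 + cx[4L] * m2 + cx[5L] * m3,
           cz[1L] * x + cz[2L] * z + cz[3L] * m1 + cz[4L] * m2 + cz[5L] * m3))
  }
  times <- seq(0, settings$t_end, by = settings$sample_dt)
  sol <- deSolve::lsoda(init, times, rhs, parms = NULL,
                        rtol = settings$rel_tol, atol = settings$abs_tol,
                        maxsteps = settings$max_steps)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1L] < 0) {
    stop(sprintf("integration failed at t = %.6g (solver state %d)",
                 max(sol[, 1L]), diagn[1L]), call. = FALSE)
  }
  if (nrow(sol) < length(times) || any(!is.finite(sol))) {
    stop(sprintf("integration produced non-finite state near t = %.6g",
                 max(sol[is.finite(rowSums(sol)), 1L])), call. = FALSE)
  }
  out <- tibble::tibble(t = sol[, 1L], x = sol[, 2L], z = sol[, 3L],
                        X_total = ss$X_s + sol[, 2L],
                        Z_total = ss$Z_s + sol[, 3L])
  attr(out, "params") <- params
  attr(out, "ss") <- ss
  attr(out, "init") <- init
  attr(out, "settings") <- settings
  # diagnostic only: the model does not constrain totals to stay nonnegative
  attr(out, "negative_totals") <- any(out$X_total < 0) || any(out$Z_total < 0)
  class(out) <- c("fluct_traj", class(out))
  out
}

#' Phase-plane orbit of a trajectory
#'
#' @param traj A `"fluct_traj"` tibble.
#' @return A tibble with the reconstructed totals `(X_total, Z_total)` in
#'   sample order, for parametric (phase-plane) plotting.
#' @export
orbit <- function(traj) {
  stopifnot(inherits(traj, "fluct_traj"))
  tibble::tibble(X_total = traj$X_total, Z_total = traj$Z_total)
}

#' Write / read a trajectory at full double precision
#'
#' Export is a CSV with columns `t, x, z, X_total, Z_total` (printed with 17
#' significant digits, which round-trips IEEE doubles losslessly) plus a JSON
#' sidecar (`<path>.json`) carrying the generating parameters, steady state,
#' initial condition and solver settings.
#'
#' @param traj A `"fluct_traj"` tibble.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   the reconstructed `"fluct_traj"` tibble.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "fluct_traj"))
  df <- as.data.frame(lapply(traj[c("t", "x", "z", "X_total", "Z_total")],
                             function(col) sprintf("%.17g", col)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(params = unclass(attr(traj, "params")),
               ss = unclass(attr(traj, "ss")),
               init = as.list(attr(traj, "init")),
               settings = unclass(attr(traj, "settings")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  side <- jsonlite::fromJSON(paste0(path, ".json"), simplifyVector = TRUE)
  out <- tibble::as_tibble(df)
  attr(out, "params") <- validate_params(side$params)
  attr(out, "ss") <- structure(side$ss, class = "steady_state")
  attr(out, "init") <- unlist(side$init)
  attr(out, "settings") <- do.call(solver_settings, side$settings)
  class(out) <- c("fluct_traj", class(out))
  out
}
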