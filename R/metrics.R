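#' Detect oscillation peaks in a trajectory
#'
#' Strict local maxima of the sampled fluctuation series inside the analysis
#' window, after a height filter: a maximum only counts as a peak if its
#' value exceeds `min_height_frac` of the window's largest absolute value.
#' Unfiltered local maxima are sensitive to solver-tolerance-level ripple;
#' the filter makes the count deterministic across reasonable tolerances.
#' The default window `t in [50, 1000]` starts after the oscillation (when
#' present) has initiated.
#'
#' @param traj A `"fluct_traj"` tibble.
#' @param variable Which fluctuation series to analyze, `"x"` (default,
#'   matching the published frequency analysis) or `"z"`.
#' @param window Analysis window `c(t_min, t_max)`; must be covered by the
#'   trajectory.
#' @param min_height_frac Height filter as a fraction of the window's max
#'   `|series|` (default 0.05).
#' @return A tibble of class `"fluct_peaks"` with columns `time` and
#'   `height`, and attributes `variable` and `window`.
#' @export
detect_peaks <- function(traj, variable = c("x", "z"), window = c(50, 1000),
                         min_height_frac = 0.05) {
  stopifnot(inherits(traj, "fluct_traj"), length(window) == 2L,
            window[1L] < window[2L])
  variable <- match.arg(variable)
  if (window[1L] < min(traj$t) || window[2L] > max(traj$t)) {
    stop(sprintf("window [%g, %g] lies outside the trajectory span [%g, %g]",
                 window[1L], window[2L], min(traj$t), max(traj$t)),
         call. = FALSE)
  }
  keep <- traj$t >= window[1L] & traj$t <= window[2L]
  tt <- traj$t[keep]
  series <- traj[[variable]][keep]
  n <- length(series)
  peaks <- tibble::tibble(time = numeric(0), height = numeric(0))
  if (n >= 3L) {
    i <- 2:(n - 1L)
    is_max <- series[i] > series[i - 1L] & series[i] > series[i + 1L]
    idx <- i[is_max]
    thr <- min_height_frac * max(abs(series))
    idx <- idx[series[idx] > thr]
    peaks <- tibble::tibble(time = tt[idx], height = series[idx])
  }
  attr(peaks, "variable") <- variable
  attr(peaks, "window") <- window
  class(peaks) <- c("fluct_peaks", class(peaks))
  peaks
}

#' Summarize oscillation metrics for one run
#'
#' Computes the peak-based metrics of one trajectory and classifies it.
#'
#' * `frequency` is the number of peaks divided by the window length
#'   (950 time units for the standard window).
#' * `mean_amplitude` is the average peak height, measured from the
#'   zero-fluctuation baseline (equivalently `X_total - X_s`); an empty peak
#'   set gives frequency 0 and amplitude 0, not an error.
#' * `oscillating` is the peak-persistence classification: at least
#'   `min_peaks` peaks in the window and the mean height of the peaks in the
#'   window's last quarter at least `persistence_ratio` of that in the first
#'   quarter. This separates persistent oscillation from a damped ring-down.
#' * `sustained` classifies the run against quiescence: `TRUE` when the
#'   fluctuation has failed to decay, i.e. the largest `|series|` value over
#'   the final quarter of the run still exceeds the initial fluctuation
#'   magnitude. Below the critical supply level a small seed perturbation
#'   dies away (`sustained = FALSE`); above it the trajectory departs for
#'   good, whether toward a displaced steady level or a limit cycle. This is
#'   the classifier used for onset bisection; see the methods vignette for
#'   why it, rather than peak persistence, marks the critical level.
#'
#' @inheritParams detect_peaks
#' @param min_peaks Minimum peak count for the `oscillating` classification.
#' @param persistence_ratio Late-to-early mean peak height ratio required for
#'   `oscillating`.
#' @return A one-row tibble: `p`, `n_peaks`, `frequency`, `mean_amplitude`,
#'   `oscillating`, `sustained`, `late_level`.
#' @export
summarize_oscillation <- function(traj, variable = c("x", "z"),
                                  window = c(50, 1000),
                                  min_height_frac = 0.05,
                                  min_peaks = 10,
                                  persistence_ratio = 0.25) {
  variable <- match.arg(variable)
  peaks <- detect_peaks(traj, variable, window, min_height_frac)
  n <- nrow(peaks)
  frequency <- n / diff(window)
  mean_amplitude <- if (n > 0) mean(peaks$height) else 0

  quarter <- diff(window) / 4
  early <- peaks$height[peaks$time <= window[1L] + quarter]
  late <- peaks$height[peaks$time >= window[2L] - quarter]
  oscillating <- n >= min_peaks && length(late) > 0 &&
    (length(early) == 0 || mean(late) >= persistence_ratio * mean(early))

  series <- traj[[variable]]
  span <- range(traj$t)
  tail_keep <- traj$t >= span[1L] + 0.75 * diff(span)
  late_level <- max(abs(series[tail_keep]))
  # reference for "has the perturbation decayed": the seed magnitude; for a
  # run not started from a small seed (zero first sample), a quarter of the
  # series' own extreme
  init <- attr(traj, "init")
  ref <- if (!is.null(init)) max(abs(init)) else abs(series[1L])
  if (ref == 0) ref <- 0.25 * max(abs(series))
  sustained <- late_level > ref

  tibble::tibble(p = attr(traj, "params")$p, n_peaks = n,
                 frequency = frequency, mean_amplitude = mean_amplitude,
                 oscillating = oscillating, sustained = sustained,
                 late_level = late_level)
}

#' Scan the cofactor supply level
#'
#' Runs one integration and oscillation summary per requested `p`, in input
#' order, and returns a tidy table. A failure at one `p` (for example an
#' invalid supply level) is recorded in its row and the scan continues.
#'
#' @param params Base `"signaling_params"` (its `p` is overridden per row).
#' @param p_values Supply levels to scan; an empty vector yields an empty
#'   table.
#' @param settings A [solver_settings()] list; the default horizon 2000 is
#'   ample for the standard analysis window.
#' @param init Initial fluctuations for every run.
#' @param p_c Critical level used for the `eps = p - p_c` column; defaults
#'   to this package's linear estimate [critical_p_linear()].
#' @param ... Passed on to [summarize_oscillation()] (variable, window, ...).
#' @return A tibble with one row per `p`: `p`, `eps`, `n_peaks`, `frequency`,
#'   `mean_amplitude`, `oscillating`, `sustained`, `ok`, `error`.
#' @export
scan_p <- function(params, p_values,
                   settings = solver_settings(t_end = 2000),
                   init = c(x = 1e-6, z = 1e-6), p_c = NULL, ...) {
  if (is.null(p_c)) {
    p_c <- tryCatch(critical_p_linear(params), error = function(err) NA_real_)
  }
  empty <- tibble::tibble(p = numeric(0), eps = numeric(0),
                          n_peaks = integer(0), frequency = numeric(0),
                          mean_amplitude = numeric(0), oscillating = logical(0),
                          sustained = logical(0), ok = logical(0),
                          error = character(0))
  if (length(p_values) == 0L) return(empty)
  rows <- purrr::map(p_values, function(p) {
    res <- tryCatch({
      traj <- simulate_fluctuations(set_p(params, p), init = init,
                                    settings = settings)
      sm <- summarize_oscillation(traj, ...)
      tibble::tibble(p = p, eps = p - p_c, n_peaks = sm$n_peaks,
                     frequency = sm$frequency,
                     mean_amplitude = sm$mean_amplitude,
                     oscillating = sm$oscillating, sustained = sm$sustained,
                     ok = TRUE, error = NA_character_)
    }, error = function(err) {
      tibble::tibble(p = p, eps = p - p_c, n_peaks = NA_integer_,
                     frequency = NA_real_, mean_amplitude = NA_real_,
                     oscillating = NA, sustained = NA, ok = FALSE,
                     error = conditionMessage(err))
    })
    res
  })
  dplyr::bind_rows(rows)
}

#' Critical supply level from simulation
#'
#' Bisects on the sustained/decaying classification of integrated
#' trajectories: the bracket endpoints must classify differently, and the
#' interval is halved (one integration per step) until narrower than
#' `resolution`. The result cross-checks the determinant root of the
#' linearization ([critical_p_linear()]).
#'
#' @inheritParams scan_p
#' @param bracket Two supply levels classifying differently (default the
#'   published panel pair `c(0.795, 0.81)` straddling the onset).
#' @param resolution Final bracket width (default `1e-3`).
#' @param ... Passed on to [summarize_oscillation()].
#' @return The onset estimate (bracket midpoint), a numeric scalar.
#' @export
find_critical_p_sim <- function(params, bracket = c(0.795, 0.81),
                                resolution = 1e-3,
                                settings = solver_settings(t_end = 2000),
                                init = c(x = 1e-6, z = 1e-6), ...) {
  classify <- function(p) {
    traj <- simulate_fluctuations(set_p(params, p), init = init,
                                  settings = settings)
    summarize_oscillation(traj, ...)$sustained
  }
  lo <- min(bracket)
  hi <- max(bracket)
  s_lo <- classify(lo)
  s_hi <- classify(hi)
  if (identical(s_lo, s_hi)) {
    stop(sprintf(paste0(
      "bracket endpoints classify identically (sustained = %s at p = %g ",
      "and p = %g); widen or move the bracket"), s_lo, lo, hi), call. = FALSE)
  }
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (identical(classify(mid), s_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Fit a metric against the logarithm of the distance above criticality
#'
#' Ordinary least squares of `metric = slope * ln(eps) + intercept`, the
#' log-scaling law relating oscillation frequency/amplitude to
#' `eps = p - p_c`.
#'
#' @param eps Strictly positive distances above criticality (at least 3).
#' @param metric Metric values (frequency or mean amplitude), same length.
#' @return An object of class `"log_fit"`: slope, intercept, Pearson `r` of
#'   `metric` vs `ln(eps)` (`NA`, with `degenerate = TRUE`, for constant
#'   input), `n`, and the `eps` grid. Has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @examples
#' fit_log(c(0.01, 0.05, 0.1, 0.2), 2 * log(c(0.01, 0.05, 0.1, 0.2)) + 5)
#' @export
fit_log <- function(eps, metric) {
  stopifnot(length(eps) == length(metric))
  if (length(eps) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(!is.finite(eps)) || any(eps <= 0)) {
    stop("`eps` values must be strictly positive and finite", call. = FALSE)
  }
  leps <- log(eps)
  fit <- stats::lm(metric ~ leps)
  degenerate <- stats::sd(metric) == 0 || stats::sd(leps) == 0
  r <- if (degenerate) NA_real_ else stats::cor(metric, leps)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = r, degenerate = degenerate,
                 n = length(eps), eps_grid = as.numeric(eps),
                 metric = as.numeric(metric)),
            class = "log_fit")
}

#' @export
print.log_fit <- function(x, ...) {
  cat(sprintf(
    "<log_fit>  metric = %.6g * ln(eps) + %.6g   (n = %d, r = %s%s)\n",
    x$slope, x$intercept, x$n,
    if (is.na(x$r)) "NA" else sprintf("%.4f", x$r),
    if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.log_fit <- function(x, ...) {
  tibble::tibble(term = c("ln(eps)", "(Intercept)"),
                 estimate = c(x$slope, x$intercept))
}

#' @export
glance.log_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                 n = x$n, degenerate = x$degenerate)
}

#' Export a log-scaling fit as JSON
#'
#' @param fit A `"log_fit"` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_log_fit <- function(fit, path) {
  stopifnot(inherits(fit, "log_fit"))
  jsonlite::write_json(
    list(slope = fit$slope, intercept = fit$intercept, r = fit$r,
         n = fit$n, degenerate = fit$degenerate, eps_grid = fit$eps_grid),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
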