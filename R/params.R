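#' Model parameters for the signaling fluctuation system
#'
#' Constructs and validates the full parameter set of the two-variable
#' fluctuation model. `X` denotes the signaling molecule bound to active
#' (non-hydrolyzed) cofactor, `Z` the molecule bound to hydrolyzed cofactor.
#' All kinetic coefficients are diffusion-limited composites; the
#' nonlinearity enters through the linear sensitivities (`a`-`f`) of the
#' effective diffusion coefficients to the concentration fluctuations.
#'
#' The defaults are the published simulation constants, under which the
#' quiescent steady state loses stability near `p = 0.80`.
#'
#' @param D1 Diffusion-limited assembly coefficient of `X` onto the receptor
#'   oligomer `R` (model units). Strictly positive.
#' @param D4 `X`-`X` interaction coefficient. Strictly positive.
#' @param D5 `X`-`Z` interaction coefficient. Strictly positive.
#' @param k2 Hydrolysis rate constant of the bound cofactor. Strictly positive.
#' @param a,b Fluctuation sensitivities of `D1` with respect to the `x` and
#'   `z` fluctuations. Nonnegative.
#' @param c,d Fluctuation sensitivities of `D4`. Nonnegative.
#' @param e,f Fluctuation sensitivities of `D5`. Nonnegative.
#' @param p Active-cofactor supply level, the control parameter of the model.
#'   Must satisfy `D1 * p > D5 * k2` so that the steady state `Z_s` is
#'   positive.
#' @param R Receptor oligomer concentration, held constant (the oligomer
#'   assembles and disassembles much more slowly than the monomers interact).
#'
#' @return A validated list of class `"signaling_params"`.
#' @seealso [steady_state()], [linearize()], [simulate_fluctuations()]
#' @examples
#' prm <- signaling_params()          # published constants, p = 1.0253
#' signaling_params(p = 0.81)         # just above the critical supply level
#' @export
signaling_params <- function(D1 = 0.28, D4 = 156, D5 = 156, k2 = 0.00034580,
                             a = 800, b = 656, c = 100, d = 100,
                             e = 100, f = 100, p = 1.0253, R = 1) {
  prm <- list(D1 = D1, D4 = D4, D5 = D5, k2 = k2, a = a, b = b, c = c,
              d = d, e = e, f = f, p = p, R = R)
  validate_params(structure(prm, class = "signaling_params"))
}

.param_keys <- c("D1", "D4", "D5", "k2", "a", "b", "c", "d", "e", "f", "p", "R")

#' Validate a parameter set
#'
#' Checks the model invariants: `D1`, `D4`, `D5`, `k2`, `R` strictly
#' positive; the fluctuation sensitivities `a`-`f` nonnegative; and the
#' positivity condition `D1 * p - D5 * k2 > 0` of the denominator of the
#' steady state `Z_s`.
#'
#' @param params A `"signaling_params"` object (or plain named list with
#'   exactly the twelve model keys).
#' @return `params`, unchanged, invisibly classed as `"signaling_params"`.
#' @export
validate_params <- function(params) {
  if (!is.list(params)) {
    stop("`params` must be a list of model parameters", call. = FALSE)
  }
  missing <- setdiff(.param_keys, names(params))
  if (length(missing)) {
    stop("missing model parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(params), .param_keys)
  if (length(unknown)) {
    stop("unknown model parameters: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vals <- unlist(params[.param_keys])
  if (!is.numeric(vals) || length(vals) != 12L || any(!is.finite(vals))) {
    stop("all model parameters must be finite numeric scalars", call. = FALSE)
  }
  for (key in c("D1", "D4", "D5", "k2", "R")) {
    if (params[[key]] <= 0) {
      stop("parameter `", key, "` must be strictly positive", call. = FALSE)
    }
  }
  for (key in c("a", "b", "c", "d", "e", "f")) {
    if (params[[key]] < 0) {
      stop("parameter `", key, "` must be nonnegative", call. = FALSE)
    }
  }
  den <- params$D1 * params$p - params$D5 * params$k2
  if (den <= 0) {
    stop(sprintf(paste0(
      "positivity condition of the Z_s denominator violated: ",
      "D1 * p - D5 * k2 = %.6g must be > 0 (p must exceed D5 * k2 / D1 = %.6g)"),
      den, params$D5 * params$k2 / params$D1), call. = FALSE)
  }
  invisible(structure(params[.param_keys], class = "signaling_params"))
}

#' Replace the cofactor supply level of a parameter set
#'
#' @param params A `"signaling_params"` object.
#' @param p New supply level.
#' @return A validated parameter set with `p` replaced.
#' @export
set_p <- function(params, p) {
  params$p <- p
  validate_params(params)
}

#' The published figure-panel supply levels
#'
#' The eight cofactor supply levels used for the published trajectory panels,
#' spanning the two sides of the critical level `p_c ~ 0.80`.
#'
#' @return A numeric vector of eight `p` values.
#' @export
panel_p_values <- function() {
  c(0.795, 0.81, 0.84, 0.88, 0.96, 1.00, 1.12, 1.16)
}

#' @export
print.signaling_params <- function(x, ...) {
  cat("<signaling_params>\n")
  cat(sprintf("  D1 = %g  D4 = %g  D5 = %g  k2 = %g  R = %g\n",
              x$D1, x$D4, x$D5, x$k2, x$R))
  cat(sprintf("  fluctuation sensitivities: a = %g  b = %g  c = %g  d = %g  e = %g  f = %g\n",
              x$a, x$b, x$c, x$d, x$e, x$f))
  cat(sprintf("  cofactor supply p = %g\n", x$p))
  invisible(x)
}

#' Serialize / deserialize a parameter set as flat JSON
#'
#' The interchange format is a flat JSON object with exactly the twelve model
#' keys; unknown keys are rejected on read.
#'
#' @param params A `"signaling_params"` object.
#' @param path File path. For `params_from_json()`, a path or a JSON string.
#' @return `params_to_json()` returns `path` invisibly; `params_from_json()`
#'   returns a validated `"signaling_params"` object.
#' @export
params_to_json <- function(params, path) {
  params <- validate_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("expected a JSON object of model parameters", call. = FALSE)
  validate_params(raw)
}
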