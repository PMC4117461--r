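#' Steady state of the signaling model
#'
#' Closed forms of the base-point concentrations about which the fluctuations
#' `(x, z)` are defined:
#' \deqn{X_s = k_2 / D_1, \qquad
#'       Z_s = \frac{k_2 (D_1^2 R + D_4 k_2)}{D_1 (D_1 p - D_5 k_2)}.}
#' Both are strictly positive whenever the parameter invariants hold.
#'
#' @param params A `"signaling_params"` object.
#' @return A list of class `"steady_state"` with elements `X_s` and `Z_s`.
#' @examples
#' steady_state(signaling_params())   # X_s = 1.235e-3, Z_s ~ 7.01e-4
#' @export
steady_state <- function(params) {
  params <- validate_params(params)
  X_s <- params$k2 / params$D1
  Z_s <- with(params, (k2 * (D1^2 * R + D4 * k2)) / (D1 * (D1 * p - D5 * k2)))
  structure(list(X_s = X_s, Z_s = Z_s), class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state>  X_s = %.6g   Z_s = %.6g\n", x$X_s, x$Z_s))
  invisible(x)
}

# Coefficients of the quadratic fluctuation vector field.
#
# Rows: (dx/dt, dz/dt); columns: monomials (x, z, x^2, x*z, z^2).
# The column-1/2 block is the linearization L. Kept as one function so the
# right-hand side, the Jacobian and the eigen reduction all read the same
# polynomial.
field_coefficients <- function(params, ss = steady_state(params)) {
  X <- ss$X_s
  Z <- ss$Z_s
  with(params, rbind(
    x = c(x  = -(R * (D1 - a * X) + 2 * X * D4 + D5 * Z),
          z  = p - D5 * X - b * X - d * X^2 - f * X * Z,
          x2 = R * a - D4 + 2 * c * X + e * Z,
          xz = -(D5 + R * b - e * X + f * Z),
          z2 = -f * X),
    z = c(x  = 2 * X * D4 + D5 * Z - c * X^2 - e * X * Z,
          z  = D5 * X - p + d * X^2 + f * X * Z,
          x2 = D4 - 2 * c * X - e * Z,
          xz = D5 + 2 * X * d - e * X + f * Z,
          z2 = 0)
  ))
}

# d(field_coefficients)/dp at the parameter set's own p, with the steady
# state re-evaluated consistently: X_s is p-independent and
# dZ_s/dp = -Z_s * D1 / (D1 p - D5 k2).
field_coefficients_dp <- function(params, ss = steady_state(params)) {
  X <- ss$X_s
  Zp <- -ss$Z_s * params$D1 / (params$D1 * params$p - params$D5 * params$k2)
  with(params, rbind(
    x = c(x = -D5 * Zp, z = 1 - f * X * Zp, x2 = e * Zp, xz = -f * Zp, z2 = 0),
    z = c(x = (D5 - e * X) * Zp, z = -1 + f * X * Zp, x2 = -e * Zp,
          xz = f * Zp, z2 = 0)
  ))
}

#' Right-hand side of the fluctuation kinetics
#'
#' Evaluates the quadratic polynomial vector field governing the
#' fluctuations `(x, z)` of the two signaling molecule concentrations about
#' the steady state `(X_s, Z_s)`. The origin is an exact equilibrium: every
#' term carries a factor `x` or `z`.
#'
#' @param params A `"signaling_params"` object.
#' @param state Numeric vector `c(x, z)` (or a two-column matrix of states,
#'   one row per evaluation point).
#' @param ss The steady state; recomputed from `params` by default.
#' @return A tibble with columns `dx_dt` and `dz_dt`, one row per state.
#' @export
fluctuation_rhs <- function(params, state, ss = steady_state(params)) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 1L)
  if (ncol(state) != 2L || !is.numeric(state) || any(!is.finite(state))) {
    stop("`state` must be finite numeric (x, z) pairs", call. = FALSE)
  }
  cf <- field_coefficients(params, ss)
  x <- state[, 1L]
  z <- state[, 2L]
  mono <- cbind(x, z, x^2, x * z, z^2)
  tibble::tibble(dx_dt = drop(mono %*% cf["x", ]),
                 dz_dt = drop(mono %*% cf["z", ]))
}

#' Linearization of the fluctuation field at the origin
#'
#' The 2x2 coefficient matrix of the degree-1 terms of the fluctuation
#' vector field (the Jacobian at the quiescent state). Its determinant
#' changes sign at the critical supply level `p_c`; see
#' [critical_p_linear()].
#'
#' @inheritParams fluctuation_rhs
#' @return A 2x2 numeric matrix with dimnames `(x, z)`, class
#'   `"linear_operator"`.
#' @examples
#' linearize(signaling_params(p = 0.8))   # near-singular: p ~ p_c
#' @export
linearize <- function(params, ss = steady_state(params)) {
  cf <- field_coefficients(params, ss)
  L <- cf[, c("x", "z")]
  dimnames(L) <- list(c("x", "z"), c("x", "z"))
  class(L) <- c("linear_operator", class(L))
  L
}

#' Critical cofactor supply level from the linearization
#'
#' Locates the root of `det L(p) = 0` by bracketing/bisection
#' ([stats::uniroot()]), recomputing the steady state at every trial `p`.
#' At this level the quiescent state loses linear stability: the slow
#' eigenvalue of `L` crosses zero.
#'
#' @param params A `"signaling_params"` object (its own `p` is ignored).
#' @param p_lo,p_hi Bracket endpoints. `det L` must change sign between them.
#' @param tol Absolute tolerance on the root (default `1e-6`).
#' @return The critical supply level `p_c` (numeric scalar).
#' @examples
#' critical_p_linear(signaling_params())   # ~ 0.804
#' @export
critical_p_linear <- function(params, p_lo = 0.76, p_hi = 0.86, tol = 1e-6) {
  det_at <- function(p) det(unclass(linearize(set_p(params, p))))
  d_lo <- det_at(p_lo)
  d_hi <- det_at(p_hi)
  if (!is.finite(d_lo) || !is.finite(d_hi) || sign(d_lo) == sign(d_hi)) {
    stop(sprintf(paste0(
      "det L(p) does not change sign on [%g, %g]: ",
      "det L(%g) = %.6g, det L(%g) = %.6g"),
      p_lo, p_hi, p_lo, d_lo, p_hi, d_hi), call. = FALSE)
  }
  stats::uniroot(det_at, c(p_lo, p_hi), tol = tol)$root
}
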