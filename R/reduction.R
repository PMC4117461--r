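# --- tiny bivariate polynomial kernel -------------------------------------
#
# A polynomial in (v, eps) is a plain matrix P with P[i + 1, j + 1] the
# coefficient of v^i eps^j. Only used internally by the eigen reduction;
# degrees stay tiny (<= 4 x 3), so dense matrices are the right tool.

bp_zero <- function(dv, de) matrix(0, dv + 1L, de + 1L)

bp_mono <- function(value, i, j, dv = i, de = j) {
  out <- bp_zero(max(dv, i), max(de, j))
  out[i + 1L, j + 1L] <- value
  out
}

bp_pad <- function(P, dv, de) {
  out <- bp_zero(dv, de)
  out[seq_len(nrow(P)), seq_len(ncol(P))] <- P
  out
}

bp_add <- function(A, B) {
  dv <- max(nrow(A), nrow(B)) - 1L
  de <- max(ncol(A), ncol(B)) - 1L
  bp_pad(A, dv, de) + bp_pad(B, dv, de)
}

# product truncated to v-degree <= max_v, eps-degree <= max_e
bp_mul <- function(A, B, max_v, max_e) {
  out <- bp_zero(max_v, max_e)
  for (ia in seq_len(nrow(A)) - 1L) {
    for (ja in seq_len(ncol(A)) - 1L) {
      ca <- A[ia + 1L, ja + 1L]
      if (ca == 0) next
      for (ib in seq_len(nrow(B)) - 1L) {
        iv <- ia + ib
        if (iv > max_v) break
        for (jb in seq_len(ncol(B)) - 1L) {
          je <- ja + jb
          if (je > max_e) break
          cb <- B[ib + 1L, jb + 1L]
          if (cb != 0) out[iv + 1L, je + 1L] <- out[iv + 1L, je + 1L] + ca * cb
        }
      }
    }
  }
  out
}

bp_eval <- function(P, v, eps) {
  out <- 0
  for (i in seq_len(nrow(P)) - 1L) {
    for (j in seq_len(ncol(P)) - 1L) {
      if (P[i + 1L, j + 1L] != 0) out <- out + P[i + 1L, j + 1L] * v^i * eps^j
    }
  }
  out
}

bp_monomial_label <- function(i, j) {
  mapply(function(iv, je) {
    ve <- if (iv == 1L) "v" else sprintf("v^%d", iv)
    if (je == 0L) return(ve)
    ee <- if (je == 1L) "eps" else sprintf("eps^%d", je)
    paste(ee, ve, sep = "*")
  }, i, j, USE.NAMES = FALSE)
}

# --- eigenframe at criticality --------------------------------------------

#' Linearization at the critical supply level
#'
#' Convenience delegate: [linearize()] evaluated with the supply level set to
#' `p_c`, where the matrix is near-singular (the slow eigenvalue sits at
#' zero). The reported critical level of the published parameter set is 0.8;
#' the exact determinant root of this implementation is at 0.8042.
#'
#' @param params A `"signaling_params"` object.
#' @param p_c Critical supply level (default 0.8, the published value).
#' @return A 2x2 `"linear_operator"` matrix.
#' @export
critical_matrix <- function(params, p_c = 0.8) {
  linearize(set_p(params, p_c))
}

#' Eigenvector coordinate frame
#'
#' Diagonalizes the critical linearization: new coordinates `(u, v)` are
#' defined by `(x, z) = T (u, v)` with the columns of `T` the eigenvectors.
#' `v` is the slow (critical) mode, the eigenvalue nearest zero; `u` the fast
#' mode. Eigenvectors are normalized to unit length with their first nonzero
#' component positive, fixing the frame uniquely.
#'
#' @param Lc A real 2x2 matrix (typically [critical_matrix()]).
#' @return A list of class `"eigen_frame"`: `values` (named `u`, `v`),
#'   `vectors` (columns `u`, `v`), `inverse`.
#' @export
eigen_frame <- function(Lc) {
  Lc <- unclass(Lc)
  stopifnot(is.matrix(Lc), all(dim(Lc) == 2L))
  eg <- eigen(Lc)
  if (is.complex(eg$values)) {
    stop(sprintf("eigenvalues are complex (%s); the frame requires real, distinct eigenvalues",
                 paste(format(eg$values, digits = 6), collapse = ", ")),
         call. = FALSE)
  }
  if (abs(diff(eg$values)) <= 1e-12 * max(abs(eg$values), 1e-300)) {
    stop(sprintf("eigenvalues %.6g and %.6g are not distinct (defective or near-defective matrix)",
                 eg$values[1L], eg$values[2L]), call. = FALSE)
  }
  iv <- which.min(abs(eg$values))
  iu <- 3L - iv
  Tm <- cbind(u = eg$vectors[, iu], v = eg$vectors[, iv])
  for (jcol in 1:2) {
    col <- Tm[, jcol] / sqrt(sum(Tm[, jcol]^2))
    lead <- which(abs(col) > 1e-14)[1L]
    if (col[lead] < 0) col <- -col
    Tm[, jcol] <- col
  }
  structure(list(values = c(u = eg$values[iu], v = eg$values[iv]),
                 vectors = Tm, inverse = solve(Tm)),
            class = "eigen_frame")
}

#' @export
print.eigen_frame <- function(x, ...) {
  cat(sprintf("<eigen_frame>  lambda_u = %.6g (fast)   lambda_v = %.6g (slow)\n",
              x$values["u"], x$values["v"]))
  invisible(x)
}

#' Map between physical and eigenvector coordinates
#'
#' @param frame An `"eigen_frame"`.
#' @param xz,uv Two-column matrices (or length-2 vectors) of coordinates.
#' @return The transformed coordinates, same shape.
#' @export
to_eigen_coords <- function(frame, xz) {
  if (is.null(dim(xz))) xz <- matrix(xz, nrow = 1L)
  out <- xz %*% t(frame$inverse)
  colnames(out) <- c("u", "v")
  out
}

#' @rdname to_eigen_coords
#' @export
from_eigen_coords <- function(frame, uv) {
  if (is.null(dim(uv))) uv <- matrix(uv, nrow = 1L)
  out <- uv %*% t(frame$vectors)
  colnames(out) <- c("x", "z")
  out
}

# --- transformed vector field ---------------------------------------------
#
# The fluctuation field at p = p_c + eps is expanded to first order in eps
# (both the explicit p-dependence and the p-dependence of the steady state
# Z_s are re-expanded about p_c) and rotated into the eigenframe:
#   d(u,v)/dt = (Lambda + eps M) (u,v) + quadratic terms (Q0 + eps Q1).
transformed_field <- function(params, frame = NULL, p_c = 0.8) {
  at_pc <- set_p(params, p_c)
  ss <- steady_state(at_pc)
  C0 <- field_coefficients(at_pc, ss)
  C1 <- field_coefficients_dp(at_pc, ss)
  L0 <- C0[, c("x", "z")]
  if (is.null(frame)) frame <- eigen_frame(L0)
  Tm <- frame$vectors
  Ti <- frame$inverse
  quad_rot <- function(crow) {
    Q <- matrix(c(crow["x2"], crow["xz"] / 2, crow["xz"] / 2, crow["z2"]), 2L)
    Qt <- t(Tm) %*% Q %*% Tm
    c(u2 = Qt[1L, 1L], uv = 2 * Qt[1L, 2L], v2 = Qt[2L, 2L])
  }
  list(frame = frame, p_c = p_c, params = at_pc,
       Lambda = Ti %*% L0 %*% Tm,
       M = Ti %*% C1[, c("x", "z")] %*% Tm,
       Q0 = Ti %*% rbind(quad_rot(C0["x", ]), quad_rot(C0["z", ])),
       Q1 = Ti %*% rbind(quad_rot(C1["x", ]), quad_rot(C1["z", ])))
}

# Substitute u = H(v, eps) into one component (row) of the transformed field;
# returns a bivariate polynomial in (v, eps) truncated at (max_v, max_e).
tf_component <- function(tf, row, H, max_v, max_e) {
  lin_u <- bp_add(bp_mono(tf$Lambda[row, 1L], 0L, 0L),
                  bp_mono(tf$M[row, 1L], 0L, 1L))
  lin_v <- bp_add(bp_mono(tf$Lambda[row, 2L], 1L, 0L),
                  bp_mono(tf$M[row, 2L], 1L, 1L))
  q_uu <- bp_add(bp_mono(tf$Q0[row, 1L], 0L, 0L), bp_mono(tf$Q1[row, 1L], 0L, 1L))
  q_uv <- bp_add(bp_mono(tf$Q0[row, 2L], 0L, 0L), bp_mono(tf$Q1[row, 2L], 0L, 1L))
  q_vv <- bp_add(bp_mono(tf$Q0[row, 3L], 0L, 0L), bp_mono(tf$Q1[row, 3L], 0L, 1L))
  v1 <- bp_mono(1, 1L, 0L)
  out <- bp_mul(lin_u, H, max_v, max_e)
  out <- bp_add(out, lin_v)
  out <- bp_add(out, bp_mul(q_uu, bp_mul(H, H, max_v, max_e), max_v, max_e))
  out <- bp_add(out, bp_mul(q_uv, bp_mul(H, v1, max_v, max_e), max_v, max_e))
  out <- bp_add(out, bp_mul(q_vv, bp_mul(v1, v1, max_v, max_e), max_v, max_e))
  bp_pad(out, max_v, max_e)
}

# --- adiabatic elimination of the fast mode -------------------------------

#' Eliminate the fast mode
#'
#' Expresses the fast eigenmode as a polynomial slaved to the slow mode and
#' the distance above criticality, `u = h(v, eps) = sum a_i v^k eps^l`, by
#' requiring the fast-mode equation `du/dt = 0` to hold to the stated order
#' (adiabatic elimination). The matching conditions — the coefficients of
#' every ansatz monomial in the substituted fast-mode equation must vanish —
#' form a system that is triangular in the total degree of the monomials,
#' with the fast eigenvalue on the diagonal; one elimination pass per degree
#' solves it to machine precision.
#'
#' @param params A `"signaling_params"` object.
#' @param frame Optional precomputed [eigen_frame()]; built from
#'   [critical_matrix()] otherwise.
#' @param p_c Critical supply level about which the field is expanded.
#' @param order Ansatz order `c(degree in v, degree in eps)`; default
#'   `c(2, 1)`, the minimal order feeding the six-coefficient reduced
#'   equation. All monomials `v^k eps^l` with `1 <= k <= order[1]`,
#'   `0 <= l <= order[2]` are included (a pure-`eps` term is excluded: the
#'   origin remains an equilibrium for every `eps`, so `h(0, eps) = 0`).
#' @return An object of class `"fast_elimination"`: tibble `a` of
#'   coefficients with monomial labels, the polynomial `H`, the `order`, and
#'   the transformed field.
#' @export
eliminate_fast_mode <- function(params, frame = NULL, p_c = 0.8,
                                order = c(2, 1)) {
  stopifnot(length(order) == 2L, order[1L] >= 1L, order[2L] >= 0L)
  tf <- transformed_field(params, frame, p_c)
  dv <- as.integer(order[1L])
  de <- as.integer(order[2L])
  monos <- expand.grid(i = seq_len(dv), j = 0:de)
  max_v <- 2L * dv + 1L
  max_e <- de + 2L
  build_H <- function(avec) {
    H <- bp_zero(dv, de)
    H[cbind(monos$i + 1L, monos$j + 1L)] <- avec
    H
  }
  residual <- function(avec) {
    Rbp <- tf_component(tf, 1L, build_H(avec), max_v, max_e)
    Rbp[cbind(monos$i + 1L, monos$j + 1L)]
  }
  lambda_u <- tf$Lambda[1L, 1L]
  if (abs(lambda_u) < 1e-12) {
    stop("fast eigenvalue is numerically zero; cannot slave the fast mode",
         call. = FALSE)
  }
  a <- numeric(nrow(monos))
  degree <- monos$i + monos$j
  for (d in sort(unique(degree))) {
    r <- residual(a)
    sel <- degree == d
    a[sel] <- a[sel] - r[sel] / lambda_u
  }
  r <- residual(a)
  if (max(abs(r)) > 1e-8 * abs(lambda_u) * (1 + max(abs(a)))) {
    stop("fast-mode matching left nonzero residuals at monomials ",
         paste(bp_monomial_label(monos$i, monos$j)[abs(r) > 1e-8],
               collapse = ", "), call. = FALSE)
  }
  structure(list(
    a = tibble::tibble(term = bp_monomial_label(monos$i, monos$j),
                       v_deg = monos$i, eps_deg = monos$j, value = a),
    H = build_H(a), order = c(dv, de), tf = tf),
    class = "fast_elimination")
}

#' @export
print.fast_elimination <- function(x, ...) {
  cat(sprintf("<fast_elimination>  order (%d, %d) about p_c = %g\n",
              x$order[1L], x$order[2L], x$tf$p_c))
  cat(paste0("  u = ", paste(sprintf("%.6g %s", x$a$value, x$a$term),
                             collapse = " + "), "\n"))
  invisible(x)
}

#' @export
tidy.fast_elimination <- function(x, ...) x$a

#' Residual of the fast-mode equation after elimination
#'
#' Evaluates the substituted fast-mode equation at the given `(v, eps)`
#' points; by construction the result is higher-order than the ansatz in
#' `(|v| + eps)`.
#'
#' @param elim A `"fast_elimination"` object.
#' @param v,eps Evaluation points (vectorized).
#' @return Numeric residuals.
#' @export
elimination_residual <- function(elim, v, eps) {
  dv <- elim$order[1L]
  de <- elim$order[2L]
  Rbp <- tf_component(elim$tf, 1L, elim$H, 2L * dv + 1L, de + 2L)
  mapply(function(vv, ee) bp_eval(Rbp, vv, ee), v, eps)
}

# --- reduced slow-mode equation -------------------------------------------

#' Reduced one-dimensional stability equation
#'
#' Substitutes the slaved fast mode `u = h(v, eps)` into the slow-mode
#' component of the transformed field, expands, and truncates to total
#' degree 3. Six coefficients `n_1..n_6` remain, on the monomial basis
#' `v, eps*v, eps^2*v, v^2, eps*v^2, v^3`:
#' \deqn{dv/dt = (n_1 + n_2 \epsilon + n_3 \epsilon^2) v
#'             + (n_4 + n_5 \epsilon) v^2 + n_6 v^3.}
#' Every term carries a factor `v`: the quiescent state `v = 0` is an
#' equilibrium at all `eps` (the constant-in-`v` row is checked to vanish).
#'
#' @param elim A `"fast_elimination"` object (or a `"signaling_params"`
#'   object, in which case the default-order elimination is run first).
#' @param ... Passed to [eliminate_fast_mode()] when `elim` is a parameter
#'   set.
#' @return An object of class `"reduced_model"`: named coefficients `n`, the
#'   full truncated polynomial, and the upstream elimination.
#' @export
reduce_slow_mode <- function(elim, ...) {
  if (inherits(elim, "signaling_params")) {
    elim <- eliminate_fast_mode(elim, ...)
  }
  stopifnot(inherits(elim, "fast_elimination"))
  fv <- tf_component(elim$tf, 2L, elim$H, 3L, 2L)
  # keep total degree <= 3 with at least one factor of v
  poly <- bp_zero(3L, 2L)
  keep <- rbind(c(1L, 0L), c(1L, 1L), c(1L, 2L), c(2L, 0L), c(2L, 1L), c(3L, 0L))
  poly[keep + 1L] <- fv[keep + 1L]
  const_row <- max(abs(fv[1L, ]))
  n <- stats::setNames(fv[keep + 1L],
                       bp_monomial_label(keep[, 1L], keep[, 2L]))
  structure(list(n = n, poly = poly, const_row = const_row, elim = elim,
                 frame = elim$tf$frame, p_c = elim$tf$p_c,
                 order = elim$order),
            class = "reduced_model")
}

#' @export
print.reduced_model <- function(x, ...) {
  cat(sprintf("<reduced_model>  order (%d, %d) about p_c = %g\n",
              x$order[1L], x$order[2L], x$p_c))
  cat(paste0("  dv/dt = ",
             paste(sprintf("%.6g %s", x$n, names(x$n)), collapse = " + "),
             "\n"))
  invisible(x)
}

#' @export
tidy.reduced_model <- function(x, ...) {
  tibble::tibble(term = names(x$n), estimate = unname(x$n))
}

#' Real equilibria of the reduced equation
#'
#' All real roots of the degree-3 fixed-point polynomial in `v` at a given
#' `eps`: the zero root (always present) plus the real roots of the
#' remaining quadratic factor, found from its discriminant. Roots with
#' `|v| > 1e-12` are labeled nonzero; a double root at a fold is counted
#' once.
#'
#' @param model A `"reduced_model"`.
#' @param eps Distance of the supply level from `p_c` (scalar; negative
#'   values probe below criticality).
#' @return A tibble with columns `v` and `nonzero`, sorted by `v`.
#' @export
v_equilibria <- function(model, eps) {
  stopifnot(inherits(model, "reduced_model"), length(eps) == 1L,
            is.finite(eps))
  n <- model$n
  c1 <- n[["v"]] + n[["eps*v"]] * eps + n[["eps^2*v"]] * eps^2
  c2 <- n[["v^2"]] + n[["eps*v^2"]] * eps
  c3 <- n[["v^3"]]
  roots <- 0
  if (c3 != 0) {
    disc <- c2^2 - 4 * c3 * c1
    if (disc > 0) {
      roots <- c(roots, (-c2 + sqrt(disc)) / (2 * c3),
                 (-c2 - sqrt(disc)) / (2 * c3))
    } else if (disc == 0) {
      roots <- c(roots, -c2 / (2 * c3))
    }
  } else if (c2 != 0) {
    roots <- c(roots, -c1 / c2)
  }
  roots <- sort(unique(roots))
  tibble::tibble(v = roots, nonzero = abs(roots) > 1e-12)
}

#' Map reduced-equation equilibria back to physical amplitudes
#'
#' Each equilibrium `v*` corresponds, through the slaving `u = h(v, eps)`
#' and the eigenframe, to fluctuation amplitudes `(x, z)`; nonzero `v` roots
#' yield nonzero physical amplitudes.
#'
#' @inheritParams v_equilibria
#' @return A tibble with columns `v`, `nonzero`, `x`, `z`.
#' @export
branch_amplitudes <- function(model, eps) {
  eq <- v_equilibria(model, eps)
  u <- vapply(eq$v, function(vv) bp_eval(model$elim$H, vv, eps), numeric(1L))
  xz <- from_eigen_coords(model$frame, cbind(u, eq$v))
  eq$x <- xz[, "x"]
  eq$z <- xz[, "z"]
  eq
}

#' Nonzero-root count across an `eps` grid
#'
#' @param model A `"reduced_model"`.
#' @param eps_grid Numeric vector of `eps` values.
#' @return A tibble `eps`, `n_nonzero`.
#' @export
root_count_profile <- function(model, eps_grid) {
  tibble::tibble(
    eps = eps_grid,
    n_nonzero = vapply(eps_grid,
                       function(e) sum(v_equilibria(model, e)$nonzero),
                       integer(1L)))
}

#' Threshold of the root-structure change (amplitude bifurcation)
#'
#' Bisects on the count of nonzero real roots of the reduced fixed-point
#' equation over `[eps_lo, eps_hi]`, locating the `eps` at which nonzero
#' equilibria appear or disappear (the amplitude bi-stability threshold).
#' The endpoint counts must differ. Also tabulates the root branches on a
#' grid for a bifurcation diagram.
#'
#' @param model A `"reduced_model"`.
#' @param eps_lo,eps_hi Search interval. `eps_lo = 0` is evaluated as the
#'   limit from above. Negative values probe below criticality, where the
#'   published parameter set's nonzero branch pair is actually born.
#' @param rel_tol Relative bisection tolerance on `eps_star` (default 1e-3).
#' @param grid_points Number of grid points for the branch diagram.
#' @return An object of class `"bifurcation"`: `eps_star`, endpoint counts,
#'   `branches` (tibble `eps`, `v`, `nonzero`), `counts` (tibble `eps`,
#'   `n_nonzero`).
#' @export
bifurcation_threshold <- function(model, eps_lo = 0, eps_hi = 0.25,
                                  rel_tol = 1e-3, grid_points = 80) {
  stopifnot(inherits(model, "reduced_model"), eps_lo < eps_hi)
  count_at <- function(e) sum(v_equilibria(model, e)$nonzero)
  lo <- if (eps_lo == 0) 1e-12 else eps_lo
  hi <- eps_hi
  c_lo <- count_at(lo)
  c_hi <- count_at(hi)
  if (c_lo == c_hi) {
    stop(sprintf(paste0(
      "nonzero-real-root count does not change on [%g, %g]: ",
      "%d roots at both ends"), eps_lo, eps_hi, c_lo), call. = FALSE)
  }
  while (abs(hi - lo) > rel_tol * max(abs(lo), abs(hi))) {
    mid <- (lo + hi) / 2
    if (count_at(mid) == c_lo) lo <- mid else hi <- mid
  }
  eps_star <- (lo + hi) / 2
  grid <-
    if (eps_lo > 0 || (eps_lo == 0 && eps_hi > 0)) {
      exp(seq(log(max(lo * 0 + 1e-6, if (eps_lo == 0) 1e-6 else eps_lo)),
              log(eps_hi), length.out = grid_points))
    } else {
      seq(eps_lo, eps_hi, length.out = grid_points)
    }
  branches <- dplyr::bind_rows(lapply(grid, function(e) {
    eq <- v_equilibria(model, e)
    eq$eps <- e
    eq
  }))[, c("eps", "v", "nonzero")]
  structure(list(eps_star = eps_star, count_lo = c_lo, count_hi = c_hi,
                 eps_lo = eps_lo, eps_hi = eps_hi,
                 branches = branches,
                 counts = root_count_profile(model, grid)),
            class = "bifurcation")
}

#' Locate the root-structure change nearest criticality
#'
#' Scans the nonzero-real-root count of the reduced fixed-point equation on
#' a log-spaced `|eps|` grid, first above criticality (`eps > 0`) and then
#' below (`eps < 0`), and bisects inside the first grid interval where the
#' count changes — i.e. the threshold closest to `eps = 0`. For the
#' published constants the count is constant (two nonzero roots, the two
#' displaced branches) everywhere above criticality; the pair is born at a
#' fold a few times `1e-3` *below* criticality.
#'
#' @param model A `"reduced_model"`.
#' @param eps_max Largest `|eps|` scanned on either side.
#' @param n_scan Grid points per side.
#' @param rel_tol Bisection tolerance, as in [bifurcation_threshold()].
#' @return A `"bifurcation"` object with an extra element `side`
#'   (`"above"` or `"below"` criticality).
#' @export
find_bifurcation <- function(model, eps_max = 0.25, n_scan = 400,
                             rel_tol = 1e-3) {
  for (side in c(1, -1)) {
    grid <- side * exp(seq(log(1e-6), log(eps_max), length.out = n_scan))
    counts <- root_count_profile(model, grid)$n_nonzero
    change <- which(diff(counts) != 0)
    if (length(change)) {
      i <- change[1L]  # grid is ordered by |eps|, so this is nearest zero
      bif <- bifurcation_threshold(model, min(grid[i], grid[i + 1L]),
                                   max(grid[i], grid[i + 1L]),
                                   rel_tol = rel_tol)
      bif$side <- if (side > 0) "above" else "below"
      return(bif)
    }
  }
  stop(sprintf(paste0(
    "nonzero-real-root count is constant for 1e-6 <= |eps| <= %g ",
    "on both sides of criticality"), eps_max), call. = FALSE)
}

#' @export
print.bifurcation <- function(x, ...) {
  cat(sprintf(
    "<bifurcation>  nonzero-root count %d -> %d across eps_star = %.6g on [%g, %g]\n",
    x$count_lo, x$count_hi, x$eps_star, x$eps_lo, x$eps_hi))
  invisible(x)
}

#' @export
tidy.bifurcation <- function(x, ...) x$branches

#' @export
glance.bifurcation <- function(x, ...) {
  tibble::tibble(eps_star = x$eps_star, count_lo = x$count_lo,
                 count_hi = x$count_hi, eps_lo = x$eps_lo, eps_hi = x$eps_hi)
}

# --- JSON / CSV export -----------------------------------------------------

#' Export the reduction as JSON / the diagram as CSV
#'
#' @param model A `"reduced_model"`.
#' @param bif A `"bifurcation"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reduced_model <- function(model, path) {
  stopifnot(inherits(model, "reduced_model"))
  jsonlite::write_json(list(
    p_c = model$p_c,
    order = model$order,
    eigenvalues = as.list(model$frame$values),
    elimination = list(term = model$elim$a$term, value = model$elim$a$value),
    n = list(term = names(model$n), value = unname(model$n)),
    const_row_residual = model$const_row
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reduced_model
#' @export
write_bifurcation <- function(bif, path) {
  stopifnot(inherits(bif, "bifurcation"))
  jsonlite::write_json(list(
    eps_star = bif$eps_star, count_lo = bif$count_lo,
    count_hi = bif$count_hi, eps_lo = bif$eps_lo, eps_hi = bif$eps_hi,
    eps_grid = bif$counts$eps, root_counts = bif$counts$n_nonzero
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reduced_model
#' @export
write_bifurcation_diagram <- function(bif, path) {
  stopifnot(inherits(bif, "bifurcation"))
  wide <- bif$branches |>
    dplyr::group_by(.data$eps) |>
    dplyr::arrange(.data$v, .by_group = TRUE) |>
    dplyr::mutate(slot = paste0("root_", dplyr::row_number())) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(id_cols = "eps", names_from = "slot",
                       values_from = "v")
  wide$count <- bif$counts$n_nonzero[match(wide$eps, bif$counts$eps)]
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
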