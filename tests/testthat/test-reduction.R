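# a hand-built reduced model with prescribed coefficients, for closed-form
# root-structure cases
toy_reduced <- function(v = 0, eps_v = 0, eps2_v = 0, v2 = 0, eps_v2 = 0,
                        v3 = 0) {
  structure(list(n = c("v" = v, "eps*v" = eps_v, "eps^2*v" = eps2_v,
                       "v^2" = v2, "eps*v^2" = eps_v2, "v^3" = v3)),
            class = "reduced_model")
}

test_that("the eigenframe fixes ordering, normalization and similarity", {
  fr <- eigen_frame(diag(c(-1, 0)))
  expect_equal(unname(fr$values), c(-1, 0))
  expect_equal(unname(fr$vectors), diag(2))   # v aligned with the null mode
  Lc <- unclass(critical_matrix(fig2_params(), 0.8))
  fr2 <- eigen_frame(Lc)
  expect_lt(abs(fr2$values["v"]), 0.01)
  expect_lt(fr2$values["u"], -0.1)
  D <- fr2$inverse %*% Lc %*% fr2$vectors
  expect_equal(D, diag(fr2$values), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(max(abs(D - diag(diag(D)))), 0, tolerance = 1e-10)
  # eigenvector identity L l_i = lambda_i l_i
  expect_equal(Lc %*% fr2$vectors, fr2$vectors %*% diag(fr2$values),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sqrt(colSums(fr2$vectors^2)), c(u = 1, v = 1))
})

test_that("the eigenframe rejects complex or defective spectra", {
  expect_error(eigen_frame(matrix(c(0, 1, -1, 0), 2)), "complex")
  expect_error(eigen_frame(matrix(c(1, 0, 1, 1), 2)), "not distinct")
})

test_that("coordinate transforms invert each other", {
  fr <- eigen_frame(unclass(critical_matrix(fig2_params(), 0.8)))
  pts <- matrix(rnorm(20, sd = 1e-3), ncol = 2)
  expect_equal(from_eigen_coords(fr, to_eigen_coords(fr, pts)), pts,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fast-mode elimination satisfies its matching conditions", {
  elim <- eliminate_fast_mode(fig2_params())
  expect_equal(elim$order, c(2L, 1L))
  # no linear-in-v slaving at criticality: the frame decouples degree one
  a_v <- elim$a$value[elim$a$term == "v"]
  expect_lt(abs(a_v), 1e-10)
  # the substituted fast-mode equation is higher-order on a shrinking box
  r1 <- abs(elimination_residual(elim, 1e-3, 1e-3))
  r2 <- abs(elimination_residual(elim, 1e-4, 1e-4))
  r3 <- abs(elimination_residual(elim, 1e-5, 1e-5))
  expect_lt(r2 / r1, 5e-3)   # ~ s^3 scaling under s = 0.1
  expect_lt(r3 / r2, 5e-3)
})

test_that("elimination coefficients are stable across ansatz orders", {
  e21 <- eliminate_fast_mode(fig2_params(), order = c(2, 1))
  e31 <- eliminate_fast_mode(fig2_params(), order = c(3, 1))
  shared <- intersect(e21$a$term, e31$a$term)
  expect_equal(e31$a$value[match(shared, e31$a$term)],
               e21$a$value[match(shared, e21$a$term)], tolerance = 1e-6)
})

test_that("the reduced equation has six coefficients and a v = 0 fixed point", {
  model <- reduce_slow_mode(eliminate_fast_mode(fig2_params()))
  expect_length(model$n, 6L)
  expect_named(model$n, c("v", "eps*v", "eps^2*v", "v^2", "eps*v^2", "v^3"))
  expect_lt(model$const_row, 1e-10)
  # linear coefficient is the slow eigenvalue at criticality
  expect_equal(unname(model$n["v"]), unname(model$frame$values["v"]),
               tolerance = 1e-10)
  eq <- v_equilibria(model, 0.01)
  expect_true(any(eq$v == 0))
  expect_equal(sum(eq$nonzero), 2L)
})

test_that("zeroed slaving reduces to the bare slow component", {
  elim <- eliminate_fast_mode(fig2_params())
  elim$H[] <- 0
  bare <- reduce_slow_mode(elim)
  # without slaving no v^3 or eps^2 v terms can arise from the quadratics
  expect_equal(unname(bare$n["v^3"]), 0)
  expect_equal(unname(bare$n["eps^2*v"]), 0)
  expect_equal(unname(bare$n["v"]), unname(bare$frame$values["v"]),
               tolerance = 1e-12)
})

test_that("reduced-equation equilibria match the full model's branches", {
  # independent oracle: Newton on the full quadratic field at p = p_c + eps
  eps <- 0.01
  prm <- set_p(fig2_params(), 0.8 + eps)
  newton_branch <- function(start) {
    y <- start
    for (i in 1:80) {
      f <- fluctuation_rhs(prm, y)
      J <- fd_jacobian(prm, y, h = 1e-9)
      y <- y - solve(J, c(f$dx_dt, f$dz_dt))
    }
    y
  }
  oracle <- newton_branch(c(1e-4, 1e-4))
  model <- reduce_slow_mode(eliminate_fast_mode(fig2_params()))
  br <- branch_amplitudes(model, eps)
  positive <- br[br$nonzero & br$v > 0, ]
  expect_equal(positive$x, oracle[1], tolerance = 0.05)
  expect_equal(positive$z, oracle[2], tolerance = 0.05)
  # nonzero v roots map to nonzero physical amplitudes
  nz <- br[br$nonzero, ]
  expect_true(all(abs(nz$x) > 0 & abs(nz$z) > 0))
})

test_that("root finding handles the closed-form cubics", {
  pitchfork <- toy_reduced(v = 1, v3 = -1)      # dv/dt = v - v^3
  eq <- v_equilibria(pitchfork, 0)
  expect_equal(eq$v, c(-1, 0, 1))
  expect_equal(sum(eq$nonzero), 2L)
  stable <- toy_reduced(v = -1, v3 = -1)        # dv/dt = -v - v^3
  eq2 <- v_equilibria(stable, 0)
  expect_equal(eq2$v, 0)
  expect_equal(sum(eq2$nonzero), 0L)
  # a fold double root is counted once
  fold <- toy_reduced(v = -1, v2 = 2, v3 = -1)  # -(v - 1)^2 v
  expect_equal(sum(v_equilibria(fold, 0)$nonzero), 1L)
})

test_that("bifurcation bisection recovers a closed-form threshold", {
  # dv/dt = (eps* - eps) v - v^3: nonzero roots exist exactly for eps < 0.1
  toy <- toy_reduced(v = 0.1, eps_v = -1, v3 = -1)
  bif <- bifurcation_threshold(toy, 0, 0.25)
  expect_equal(bif$eps_star, 0.1, tolerance = 2e-3)
  expect_equal(bif$count_lo, 2L)
  expect_equal(bif$count_hi, 0L)
  tight <- bifurcation_threshold(toy, 0, 0.25, rel_tol = 1e-4)
  expect_lt(abs(tight$eps_star - bif$eps_star) / tight$eps_star, 1e-2)
  expect_error(bifurcation_threshold(toy_reduced(v = -1, v3 = -1), 0, 0.25),
               "does not change")
})

test_that("the published constants place the root-structure change below criticality", {
  model <- reduce_slow_mode(eliminate_fast_mode(fig2_params()))
  # above criticality both displaced branches persist across the whole range
  prof <- root_count_profile(model, c(1e-5, 1e-4, 1e-3, 0.01, 0.1, 0.25))
  expect_true(all(prof$n_nonzero == 2L))
  bif <- find_bifurcation(model)
  expect_equal(bif$side, "below")
  expect_lt(bif$eps_star, 0)
  expect_equal(sort(c(bif$count_lo, bif$count_hi)), c(0L, 2L))
  # the change nearest criticality sits a few 1e-3 below it
  expect_gt(abs(bif$eps_star), 1e-3)
  expect_lt(abs(bif$eps_star), 1e-2)
})
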