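test_that("parameter validation enforces the model invariants", {
  expect_s3_class(fig2_params(1.0253), "signaling_params")
  # supply level too low for a positive Z_s: D5 * k2 / D1 ~ 0.1927 > 0.19
  expect_error(signaling_params(p = 0.19), "Z_s denominator")
  expect_error(signaling_params(k2 = 0), "strictly positive")
  expect_error(signaling_params(a = -1), "nonnegative")
  expect_error(validate_params(c(unclass(signaling_params()), list(q = 1))),
               "unknown model parameters")
  expect_error(validate_params(list(D1 = 0.28)), "missing model parameters")
  expect_error(signaling_params(p = Inf), "finite")
})

test_that("steady state matches the closed forms", {
  prm <- fig2_params(1.0253)
  ss <- steady_state(prm)
  # independent arithmetic on the printed constants
  expect_equal(ss$X_s, 0.00034580 / 0.28, tolerance = 1e-14)
  expect_equal(ss$X_s, 1.2350e-3, tolerance = 1e-4)
  z_oracle <- 0.00034580 * (0.28^2 * 1 + 156 * 0.00034580) /
    (0.28 * (0.28 * 1.0253 - 156 * 0.00034580))
  expect_equal(ss$Z_s, z_oracle, tolerance = 1e-14)
  expect_equal(ss$Z_s, 7.0107e-4, tolerance = 1e-4)
  expect_true(ss$X_s > 0 && ss$Z_s > 0)
})

test_that("steady state identity X_s * D1 = k2 holds to machine precision", {
  for (i in 1:25) {
    prm <- random_valid_params()
    expect_equal(steady_state(prm)$X_s * prm$D1, prm$k2,
                 tolerance = 1e-15)
  }
})

test_that("steady state vanishes in the k2 -> 0 limit", {
  prm <- signaling_params(k2 = 1e-12)
  ss <- steady_state(prm)
  expect_lt(ss$X_s, 1e-10)
  expect_lt(ss$Z_s, 1e-10)
})

test_that("the origin is an exact equilibrium of the fluctuation field", {
  for (i in 1:100) {
    prm <- random_valid_params()
    rhs <- fluctuation_rhs(prm, c(0, 0))
    expect_identical(rhs$dx_dt, 0)
    expect_identical(rhs$dz_dt, 0)
  }
})

test_that("the vector field matches an independent term-by-term evaluation", {
  prm <- fig2_params(1.0253)
  ss <- steady_state(prm)
  X <- ss$X_s; Z <- ss$Z_s
  x <- 1e-6; z <- 1e-6
  # spelled-out polynomial, evaluated term by term with the raw constants
  dx <- -(1 * (0.28 - 800 * X) + 2 * X * 156 + 156 * Z) * x +
    (1 * 800 - 156 + 2 * 100 * X + 100 * Z) * x^2 +
    (1.0253 - 156 * X - 656 * X - 100 * X^2 - 100 * X * Z) * z -
    (156 + 1 * 656 - 100 * X + 100 * Z) * x * z -
    (100 * X) * z^2
  dz <- (2 * X * 156 + 156 * Z - 100 * X^2 - 100 * X * Z) * x +
    (156 - 2 * 100 * X - 100 * Z) * x^2 +
    (156 + 2 * X * 100 - 100 * X + 100 * Z) * x * z +
    (156 * X - 1.0253 + 100 * X^2 + 100 * X * Z) * z
  rhs <- fluctuation_rhs(prm, c(x, z))
  expect_equal(rhs$dx_dt, dx, tolerance = 1e-12)
  expect_equal(rhs$dz_dt, dz, tolerance = 1e-12)
  expect_error(fluctuation_rhs(prm, c(NaN, 0)), "finite")
})

test_that("linearization agrees with finite differences at the origin", {
  for (i in 1:100) {
    prm <- random_valid_params()
    L <- unclass(linearize(prm))
    expect_equal(L, fd_jacobian(prm), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("directional limit of the field reproduces the first column of L", {
  prm <- fig2_params(1.0)
  L <- unclass(linearize(prm))
  delta <- 1e-7
  up <- fluctuation_rhs(prm, c(delta, 0))
  dn <- fluctuation_rhs(prm, c(-delta, 0))
  # central difference: the even (quadratic) terms cancel exactly
  expect_equal(c(up$dx_dt - dn$dx_dt, up$dz_dt - dn$dz_dt) / (2 * delta),
               L[, 1], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("linearization with zeroed sensitivities and base point is triangular", {
  prm <- signaling_params(a = 0, b = 0, c = 0, d = 0, e = 0, f = 0, p = 1.0)
  ss0 <- structure(list(X_s = 0, Z_s = 0), class = "steady_state")
  L <- unclass(linearize(prm, ss0))
  expect_equal(L, matrix(c(-prm$R * prm$D1, 0, prm$p, -prm$p), 2),
               ignore_attr = TRUE)
})

test_that("the critical matrix is near-singular at the published p_c", {
  L <- critical_matrix(fig2_params(), p_c = 0.8)
  expect_lt(abs(det(unclass(L))), 0.01)
  ev <- eigen(unclass(L))$values
  expect_true(all(Im(ev) == 0))
  expect_lt(min(abs(ev)), 0.01)
  expect_lt(sum(diag(unclass(L))), 0)   # trace negative: one stable mode
  expect_equal(unclass(critical_matrix(fig2_params(), 0.81)),
               unclass(linearize(set_p(fig2_params(), 0.81))))
})

test_that("the determinant root locates the critical supply level", {
  prm <- fig2_params()
  p_c <- critical_p_linear(prm, 0.76, 0.86)
  expect_equal(p_c, 0.80417, tolerance = 1e-4)
  # the published onset claim brackets it
  expect_gt(p_c, 0.795)
  expect_lt(p_c, 0.81)
  # a tight bracket still contains a sign change
  expect_equal(critical_p_linear(prm, 0.795, 0.81), p_c, tolerance = 1e-5)
  expect_error(critical_p_linear(prm, 0.9, 1.0), "does not change sign")
})

test_that("det L(p) decreases across the scanned supply range", {
  prm <- fig2_params()
  grid <- seq(0.76, 1.05, by = 0.01)
  dets <- vapply(grid, function(p) det(unclass(linearize(set_p(prm, p)))),
                 numeric(1))
  expect_true(all(diff(dets) < 0))
})

test_that("parameters round-trip through flat JSON with strict keys", {
  prm <- fig2_params(0.81)
  path <- withr::local_tempfile(fileext = ".json")
  params_to_json(prm, path)
  expect_equal(params_from_json(path), prm)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"D1": 0.28, "bogus": 1}', bad)
  expect_error(params_from_json(bad), "unknown|missing")
})
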