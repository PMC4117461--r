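# Shared fixtures: the published constant set, a trajectory cache (several
# tests analyze the same runs), synthetic trajectories built in code, and a
# generator of random valid parameter sets for property-style tests.

fig2_params <- function(p = 1.0253) set_p(signaling_params(), p)

.traj_cache <- new.env(parent = emptyenv())

cached_traj <- function(p, t_end = 2000, rel_tol = 1e-8, abs_tol = 1e-10) {
  key <- paste(p, t_end, rel_tol, abs_tol, sep = "|")
  if (is.null(.traj_cache[[key]])) {
    .traj_cache[[key]] <- simulate_fluctuations(
      fig2_params(p),
      settings = solver_settings(t_end = t_end, sample_dt = 0.1,
                                 rel_tol = rel_tol, abs_tol = abs_tol))
  }
  .traj_cache[[key]]
}

# a hand-built trajectory object around arbitrary series values
synthetic_traj <- function(t, x, z = rep(0, length(t)),
                           params = fig2_params(1.0)) {
  ss <- steady_state(params)
  out <- tibble::tibble(t = t, x = x, z = z,
                        X_total = ss$X_s + x, Z_total = ss$Z_s + z)
  attr(out, "params") <- params
  attr(out, "ss") <- ss
  attr(out, "init") <- c(x = x[1], z = z[1])
  attr(out, "settings") <- solver_settings(
    t_end = max(max(t), 0.1),
    sample_dt = if (length(t) > 1) diff(t[1:2]) else 0.1)
  class(out) <- c("fluct_traj", class(out))
  out
}

sine_traj <- function(period = 10, dt = 0.01, t_max = 1050, amplitude = 1) {
  t <- seq(0, t_max, by = dt)
  synthetic_traj(t, amplitude * sin(2 * pi * t / period))
}

random_valid_params <- function() {
  repeat {
    prm <- try(signaling_params(
      D1 = runif(1, 0.1, 1), D4 = runif(1, 50, 300), D5 = runif(1, 50, 300),
      k2 = runif(1, 1e-4, 1e-3), a = runif(1, 0, 900), b = runif(1, 0, 900),
      c = runif(1, 0, 300), d = runif(1, 0, 300), e = runif(1, 0, 300),
      f = runif(1, 0, 300), p = runif(1, 0.5, 1.5), R = runif(1, 0.5, 2)),
      silent = TRUE)
    if (!inherits(prm, "try-error")) return(prm)
  }
}

# central finite-difference Jacobian of the fluctuation field at a point
fd_jacobian <- function(params, at = c(0, 0), h = 1e-7) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    up <- at; up[j] <- up[j] + h
    dn <- at; dn[j] <- dn[j] - h
    fu <- fluctuation_rhs(params, up)
    fd <- fluctuation_rhs(params, dn)
    J[, j] <- c(fu$dx_dt - fd$dx_dt, fu$dz_dt - fd$dz_dt) / (2 * h)
  }
  J
}
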