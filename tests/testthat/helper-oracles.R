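# Independent oracles used across tests; none of these call the solver
# paths they are used to check.

# Damped fixed-point iteration on the self-consistent production rate,
# independent of the bisection solver.
oracle_kn_fixed_point <- function(p, damping = 0.5, n_iter = 5000) {
  cmn <- p$alpha_y / p$alpha_m
  F <- function(kn) {
    NXp <- p$NXt - kn * (1 / p$alpha_x + 1 / p$beta_x)
    NYp <- p$NYt - kn / p$alpha_y
    if (NXp <= 0 || NYp <= 0) return(0)
    p$k0 * p$Vn / (p$Vn + p$Kv) * p$Km / (cmn + p$Km) *
      (NXp / p$Vn) / (NXp / p$Vn + p$Kx) *
      (NYp / p$Vn) / (NYp / p$Vn + p$Ky)
  }
  kn <- kn_max(p) / 2
  for (i in seq_len(n_iter)) kn <- (1 - damping) * kn + damping * F(kn)
  kn
}

# Dense-grid sign-change scan of kn - F(kn); returns the crossing
# intervals (should be exactly one).
oracle_kn_grid_scan <- function(p, step_frac = 1e-4) {
  km <- min(kn_max(p), p$alpha_y * p$NYt)
  grid <- seq(0, km * (1 - 1e-9), by = step_frac * km)
  cmn <- p$alpha_y / p$alpha_m
  g <- vapply(grid, function(kn) {
    kn - rsbuffer:::steady_production(kn, p, cmn)
  }, numeric(1))
  idx <- which(diff(sign(g)) != 0)
  list(crossings = idx, lo = grid[idx], hi = grid[idx + 1])
}

# Fixed-step classical RK4 integrator over the core RHS.
oracle_rk4 <- function(p, init, t_end, dt = 0.01) {
  y <- as.numeric(init[c("Nmn", "Nmc", "NXn", "NXc", "NXp", "NYn", "NYp")])
  names(y) <- c("Nmn", "Nmc", "NXn", "NXc", "NXp", "NYn", "NYp")
  f <- function(y) unname(rs_derivatives(y, p))
  n <- ceiling(t_end / dt)
  for (i in seq_len(n)) {
    k1 <- f(y); k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2); k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# Random feasible parameter set around the basic values (lognormal
# factors); redraws until the steady-state solve succeeds.
random_feasible_params <- function(cv = 0.4) {
  base <- rs_params()
  repeat {
    fac <- stats::rlnorm(14, 0, sqrt(log(1 + cv^2)))
    q <- tryCatch(
      do.call(rs_params, as.list(unlist(base[rs_param_names()]) * fac)),
      error = function(e) NULL)
    if (is.null(q)) next
    ss <- tryCatch(rs_steady_state(q), error = function(e) NULL)
    if (!is.null(ss) && ss$state[["NXp"]] > 0 && ss$state[["NYp"]] > 0) {
      return(q)
    }
  }
}

# Random initial state consistent with the conservation totals of p.
random_consistent_state <- function(p) {
  wx <- stats::rgamma(3, 1); wx <- wx / sum(wx)
  wy <- stats::rgamma(2, 1); wy <- wy / sum(wy)
  rs_state(Nmn = stats::runif(1, 0, 2 * p$alpha_y / p$alpha_m * p$Vn),
           Nmc = stats::runif(1, 0, 2 * p$beta_x / p$beta_m * p$Vc),
           NXn = wx[1] * p$NXt, NXc = wx[2] * p$NXt, NXp = wx[3] * p$NXt,
           NYn = wy[1] * p$NYt, NYp = wy[2] * p$NYt)
}
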