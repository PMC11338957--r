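#' Screen configuration
#'
#' Settings for the in-silico genome-wide perturbation screens. Parameters
#' are drawn from mean-preserving lognormal distributions
#' (`sigma^2 = log(1 + CV^2)`, `mu = log(mean) - sigma^2/2`).
#'
#' @param n_samples Number of perturbed samples.
#' @param cv_kn_params CV for parameters entering the production law
#'   (`k0`, `Kv`, `Kx`, `Ky`, `Vn`, `Vc`); default 0.5.
#' @param cv_other CV for the remaining rate constants
#'   (`alpha_m`, `alpha_x`, `alpha_y`, `beta_m`, `beta_x`); default 0.2.
#' @param cv_totals CV for the total copy numbers `NXt`, `NYt`; default 0.5.
#' @param cv_alpha_m CV for `alpha_m` in the export-impairment screen;
#'   default 1.
#' @param mrna_noise Apply Poisson noise to mRNA copy numbers?
#' @param rate_noise_cv CV of multiplicative Gaussian noise on reported
#'   rates (0 disables); default 0.05.
#' @param seed Integer seed for all randomness.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(n_samples = 1000, cv_kn_params = 0.5,
                          cv_other = 0.2, cv_totals = 0.5, cv_alpha_m = 1,
                          mrna_noise = TRUE, rate_noise_cv = 0.05,
                          seed = 1L) {
  cvs <- c(cv_kn_params, cv_other, cv_totals, cv_alpha_m, rate_noise_cv)
  if (any(cvs < 0)) stop("CVs must be >= 0")
  if (n_samples < 1) stop("'n_samples' must be >= 1")
  structure(list(n_samples = as.integer(n_samples),
                 cv_kn_params = cv_kn_params, cv_other = cv_other,
                 cv_totals = cv_totals, cv_alpha_m = cv_alpha_m,
                 mrna_noise = isTRUE(mrna_noise),
                 rate_noise_cv = rate_noise_cv, seed = as.integer(seed)),
            class = "screen_config")
}

# Mean-preserving lognormal draw.
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Multiplicative Gaussian noise, redrawn until positive.
mult_gauss <- function(x, cv) {
  if (cv == 0) return(x)
  f <- stats::rnorm(length(x), 1, cv)
  bad <- f <= 0
  while (any(bad)) {
    f[bad] <- stats::rnorm(sum(bad), 1, cv)
    bad <- f <= 0
  }
  x * f
}

# One perturbed-parameter draw given per-field CVs (named vector).
draw_params <- function(p, cvs) {
  q <- p
  for (nm in names(cvs)) q[[nm]] <- rlnorm_cv(1, p[[nm]], cvs[[nm]])
  q
}

# Steady-state observables of one parameter set, or NULL if infeasible.
screen_observe <- function(p) {
  ss <- tryCatch(rs_steady_state(p), error = function(e) NULL)
  if (is.null(ss)) return(NULL)
  st <- ss$state
  if (st[["NXp"]] <= 0 || st[["NYp"]] <= 0) return(NULL)
  list(kn = ss$kn, delta_m = ss$delta_m,
       Nmn = st[["Nmn"]], Nmc = st[["Nmc"]], Vn = p$Vn, Vc = p$Vc)
}

run_screen_engine <- function(p, cfg, cvs) {
  p <- validate_params(p)
  base <- screen_observe(p)
  if (is.null(base)) stop("base parameter set is infeasible")
  n <- cfg$n_samples
  rows <- vector("list", n)
  rejected <- 0L
  set.seed(cfg$seed)
  for (i in seq_len(n)) {
    obs <- NULL
    while (is.null(obs)) {
      q <- draw_params(p, cvs)
      obs <- tryCatch(screen_observe(q), error = function(e) NULL)
      if (is.null(obs)) {
        rejected <- rejected + 1L
        if (rejected > n && rejected > 2 * i) {
          stop("more than 50% of parameter draws infeasible; ",
               "reduce the screen CVs", call. = FALSE)
        }
      }
    }
    Nmn <- obs$Nmn; Nmc <- obs$Nmc
    if (cfg$mrna_noise) {
      Nmn <- stats::rpois(1, Nmn)
      Nmc <- stats::rpois(1, Nmc)
    }
    kn <- mult_gauss(obs$kn, cfg$rate_noise_cv)
    dm <- mult_gauss(obs$delta_m, cfg$rate_noise_cv)
    rows[[i]] <- tibble::tibble(
      sample = i,
      kn_fold = kn / base$kn,
      delta_m_fold = dm / base$delta_m,
      cmn_fold = (Nmn / obs$Vn) / (base$Nmn / base$Vn),
      cmc_fold = (Nmc / obs$Vc) / (base$Nmc / base$Vc))
  }
  samples <- dplyr::bind_rows(rows)
  # the y = x alignment of degradation vs production folds is summarized
  # by the through-origin slope in log-fold space (scale-symmetric; the
  # linear-fold slope is also reported but is inflated by the reciprocal
  # moments of the sampled lognormals)
  lx <- log(samples$kn_fold)
  ly <- log(samples$delta_m_fold)
  summary <- tibble::tibble(
    r_kn_cmn = suppressWarnings(
      stats::cor(samples$kn_fold, samples$cmn_fold)),
    r_kn_cmc = suppressWarnings(
      stats::cor(samples$kn_fold, samples$cmc_fold)),
    slope_dm_kn = sum(lx * ly) / sum(lx^2),
    slope_dm_kn_linear = sum(samples$delta_m_fold * samples$kn_fold) /
      sum(samples$kn_fold^2),
    n_rejected = rejected)
  structure(list(samples = samples, summary = summary, base = base,
                 config = cfg),
            class = "rs_screen")
}

#' Genome-wide perturbation screen
#'
#' Draws `n_samples` perturbed parameter sets (production-law parameters
#' at `cv_kn_params`, other rates at `cv_other`, protein totals at
#' `cv_totals`), solves each steady state, applies Poisson copy-number
#' noise and multiplicative Gaussian rate noise, and reports fold changes
#' of the production rate, per-mRNA degradation rate, and nuclear and
#' cytoplasmic mRNA concentrations relative to the unperturbed base.
#' Infeasible draws are rejected and redrawn (counted in the summary).
#'
#' @param p Base `rs_params`; the screen emulation of the mammalian data
#'   uses `k0/8` (apply beforehand, e.g. `update_params(p, k0 = p$k0/8)`).
#' @param cfg A [screen_config()].
#' @return An `rs_screen` list: `samples` (per-sample fold tibble),
#'   `summary` (correlations, origin-constrained slope of degradation vs
#'   production fold, rejection count), `base`, `config`.
#' @export
run_perturbation_screen <- function(p, cfg = screen_config()) {
  cvs <- c(k0 = cfg$cv_kn_params, Kv = cfg$cv_kn_params,
           Kx = cfg$cv_kn_params, Ky = cfg$cv_kn_params,
           Vn = cfg$cv_kn_params, Vc = cfg$cv_kn_params,
           alpha_m = cfg$cv_other, alpha_x = cfg$cv_other,
           alpha_y = cfg$cv_other, beta_m = cfg$cv_other,
           beta_x = cfg$cv_other,
           NXt = cfg$cv_totals, NYt = cfg$cv_totals)
  run_screen_engine(p, cfg, cvs)
}

#' Export-impairment screen
#'
#' As [run_perturbation_screen()] but with the export rate constant
#' `alpha_m` dominant (CV `cv_alpha_m`, default 1) and all production-law
#' parameters and totals at CV `cv_other`-like 0.2; the shuttle/degradation
#' constants are left unperturbed. In noiseless mode the nuclear
#' concentration fold is exactly `alpha_m_base/alpha_m_sample` and the
#' cytoplasmic fold exactly 1.
#'
#' @inheritParams run_perturbation_screen
#' @return An `rs_screen` object.
#' @export
run_alpha_m_screen <- function(p, cfg = screen_config(cv_alpha_m = 1)) {
  if (cfg$cv_alpha_m <= 0) stop("'cv_alpha_m' must be positive")
  cvs <- c(alpha_m = cfg$cv_alpha_m,
           k0 = 0.2, Kv = 0.2, Kx = 0.2, Ky = 0.2, Vn = 0.2, Vc = 0.2,
           NXt = 0.2, NYt = 0.2)
  run_screen_engine(p, cfg, cvs)
}

#' Steady states across cell volumes
#'
#' Scales the nuclear and cytoplasmic volumes and the protein totals
#' proportionally to the total cell volume and solves the steady state at
#' each volume. The volume dependence of the production law can follow the
#' default MM form `Vn/(Vn+Kv)`, a superlinear law `1e-5 * Vn^1.5`, or an
#' oscillating law `0.05 * Vn * (sin(5 Vn) + 2)`. Concentrations are
#' volume-invariant under all three laws; the per-mRNA degradation rate
#' tracks the production rate per mRNA.
#'
#' @param p Base `rs_params` (defines the reference volume and the
#'   Vn:Vc ratio). The growth-figure emulation uses `k0/3`.
#' @param volumes Total cell volumes (fL).
#' @param scaling `"mm"`, `"superlinear"`, or `"oscillating"`.
#' @return A tibble with one row per volume: `volume`, `Vn`, `kn`,
#'   `delta_m`, `mrna_number`, `cmn`, `cmc`, `feasible`, and fold columns
#'   relative to the reference (the base volume).
#' @export
volume_scan <- function(p, volumes = rs_params()$Vn + rs_params()$Vc,
                        scaling = c("mm", "superlinear", "oscillating")) {
  scaling <- match.arg(scaling)
  p <- validate_params(p)
  if (any(volumes <= 0)) stop("'volumes' must be positive")
  v0 <- p$Vn + p$Vc
  fn_ratio <- p$Vn / v0
  one <- function(v) {
    sc <- v / v0
    q <- update_params(p, Vn = v * fn_ratio, Vc = v * (1 - fn_ratio),
                       NXt = p$NXt * sc, NYt = p$NYt * sc)
    vf <- switch(scaling,
                 mm = q$Vn / (q$Vn + q$Kv),
                 superlinear = 1e-5 * q$Vn^1.5,
                 oscillating = 0.05 * q$Vn * (sin(5 * q$Vn) + 2))
    cmn <- q$alpha_y / q$alpha_m
    g <- function(kn) kn - steady_production(kn, q, cmn, volume_factor = vf)
    hi <- min(attr(q, "kn_max"), q$alpha_y * q$NYt) * (1 - 1e-12)
    if (g(hi) < 0) {
      return(tibble::tibble(volume = v, Vn = q$Vn, kn = NA_real_,
                            delta_m = NA_real_, mrna_number = NA_real_,
                            cmn = NA_real_, cmc = NA_real_, feasible = FALSE))
    }
    kn <- stats::uniroot(g, c(0, hi), tol = 1e-13 * hi)$root
    st <- steady_state_from_kn(kn, q)
    tibble::tibble(volume = v, Vn = q$Vn, kn = kn,
                   delta_m = degradation_rate_per_mrna(st, q),
                   mrna_number = st[["Nmn"]] + st[["Nmc"]],
                   cmn = st[["Nmn"]] / q$Vn, cmc = st[["Nmc"]] / q$Vc,
                   feasible = TRUE)
  }
  out <- dplyr::bind_rows(lapply(volumes, one))
  ref <- one(v0)
  out$kn_fold <- out$kn / ref$kn
  out$delta_m_fold <- out$delta_m / ref$delta_m
  out$mrna_fold <- out$mrna_number / ref$mrna_number
  out$volume_fold <- out$volume / v0
  out
}

# First time at which `x` crosses below (or above) a level, linearly
# interpolated; NA if never.
cross_time <- function(times, x, level, below = TRUE) {
  hit <- if (below) x < level else x > level
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(times[1])
  t0 <- times[i - 1]; t1 <- times[i]
  x0 <- x[i - 1]; x1 <- x[i]
  if (x1 == x0) return(t1)
  t0 + (level - x0) / (x1 - x0) * (t1 - t0)
}

#' Acute depletion of cytoplasmic X
#'
#' Starts at the steady state, instantaneously removes the fraction `fdep`
#' of cytoplasmic X (the total X budget is reduced accordingly; nuclear X
#' pools are untouched), and integrates. The trajectory shows three
#' phases: accumulation (mRNA rises at near-constant production),
#' adaptation (production drops sharply once the nuclear TF pool of X
#' thins), and reversion (mRNA relaxes back towards baseline).
#'
#' Phase boundaries are operationalized as: accumulation ends at the first
#' crossing of `kn` below `0.95 * kn_bf`; adaptation ends when `kn` first
#' enters within 1% of its final plateau. Closed-form approximations are
#' reported alongside: `Tacc ~ (NXp* - Kx Vn) / (fdep * kn_bf)` and
#' `Trev ~ Vc / (beta_m * NXc_rev)`.
#'
#' @param p An `rs_params` object.
#' @param fdep Depleted fraction of cytoplasmic X, in (0, 1).
#' @param horizon Simulation horizon (min).
#' @param dt Output grid spacing (min).
#' @return A list of class `rs_depletion`: `trajectory` (an
#'   `rs_trajectory` with fold columns `mrna_fold`, `kn_fold`), `phases`
#'   (one-row tibble with measured `Tacc`, `Tadp`, `Trev`, the
#'   approximations, the plateau production fold and peak total-mRNA
#'   fold), `kn_bf` and the post-depletion parameter set.
#' @export
acute_depletion_timecourse <- function(p, fdep = 0.8, horizon = 600,
                                       dt = 0.5) {
  if (!is.numeric(fdep) || fdep <= 0 || fdep >= 1) {
    stop("'fdep' must lie strictly between 0 and 1")
  }
  p <- validate_params(p)
  ss <- rs_steady_state(p)
  st <- ss$state
  removed <- fdep * st[["NXc"]]
  init <- st
  init[["NXc"]] <- st[["NXc"]] - removed
  p_post <- update_params(p, NXt = p$NXt - removed)
  times <- seq(0, horizon, by = dt)
  tr <- rs_simulate(p_post, init = init, times = times)
  mrna_bf <- st[["Nmn"]] + st[["Nmc"]]
  tr$mrna_fold <- (tr$Nmn + tr$Nmc) / mrna_bf
  tr$kn_fold <- tr$kn / ss$kn
  ss_post <- rs_steady_state(p_post)
  kn_rev <- ss_post$kn
  Tacc <- cross_time(tr$time, tr$kn, 0.95 * ss$kn)
  in_band <- abs(tr$kn - kn_rev) <= 0.01 * kn_rev
  # first time kn enters the 1% plateau band and stays there
  i3 <- which(rev(cumprod(rev(in_band))) == 1)[1]
  T3 <- if (is.na(i3)) NA_real_ else tr$time[i3]
  Tadp <- T3 - Tacc
  # reversion relaxation time: exponential fit of excess mRNA after T3
  Trev <- NA_real_
  if (!is.na(T3)) {
    seg <- tr[tr$time >= T3, ]
    fit <- tryCatch(
      fit_reversion_decay(
        tibble::tibble(time = seg$time, total_fold = seg$mrna_fold),
        t_start = T3),
      error = function(e) NULL)
    if (!is.null(fit) && !isTRUE(fit$degenerate)) Trev <- 1 / fit$b
  }
  NXc_rev <- ss_post$state[["NXc"]]
  phases <- tibble::tibble(
    Tacc = Tacc, Tadp = Tadp, T3 = T3, Trev = Trev,
    Tacc_approx = (st[["NXp"]] - p$Kx * p$Vn) / (fdep * ss$kn),
    Trev_approx = p$Vc / (p$beta_m * NXc_rev),
    plateau_kn_fold = kn_rev / ss$kn,
    peak_mrna_fold = max(tr$mrna_fold))
  structure(list(trajectory = tr, phases = phases, kn_bf = ss$kn,
                 params_post = p_post, steady_pre = ss, steady_post = ss_post),
            class = "rs_depletion")
}

#' Focal-gene decay after Pol II depletion
#'
#' Tracks the mRNA of a single gene (a fraction `phi` of total production)
#' after its transcription is shut off, under the global model at steady
#' state, for a control cell and a Pol II-depleted cell (halved Pol II
#' concentration is equivalent to scaling the volume MM constant `Kv` by
#' `kv_factor`). The focal pools are passive species sharing the global
#' export and degradation fields, which remain at their steady values, so
#' the decay is a two-exponential closed form.
#'
#' @param p An `rs_params` object.
#' @param kv_factor Multiplier on `Kv` for the depleted cell (>= 1).
#' @param gene_fraction Focal gene's share of total production, `phi << 1`.
#' @param times Output time grid (min).
#' @return A tibble with `time`, `control`, `depleted` (total focal mRNA
#'   normalized to 1 at t = 0), plus attribute `rates` with the export and
#'   degradation coefficients of both conditions.
#' @export
polII_depletion_decay <- function(p, kv_factor = 2, gene_fraction = 0.01,
                                  times = seq(0, 200, by = 1)) {
  if (kv_factor < 1) stop("'kv_factor' must be >= 1")
  if (gene_fraction >= 0.1) {
    stop("'gene_fraction' must be < 0.1 (focal feedback must be negligible)")
  }
  p <- validate_params(p)
  decay_curve <- function(q) {
    ss <- rs_steady_state(q)
    a <- q$alpha_m * ss$state[["NYn"]] / q$Vn  # nuclear export coefficient
    d <- degradation_rate_per_mrna(ss$state, q)
    m0n <- gene_fraction * ss$state[["Nmn"]]
    m0c <- gene_fraction * ss$state[["Nmc"]]
    mn <- m0n * exp(-a * times)
    mc <- if (abs(a - d) > 1e-12 * max(a, d)) {
      m0c * exp(-d * times) +
        a * m0n / (d - a) * (exp(-a * times) - exp(-d * times))
    } else {
      m0c * exp(-d * times) + a * m0n * times * exp(-d * times)
    }
    list(curve = (mn + mc) / (m0n + m0c), a = a, d = d)
  }
  ctrl <- decay_curve(p)
  depl <- decay_curve(update_params(p, Kv = kv_factor * p$Kv))
  out <- tibble::tibble(time = times, control = ctrl$curve,
                        depleted = depl$curve)
  attr(out, "rates") <- tibble::tibble(
    condition = c("control", "depleted"),
    export_coef = c(ctrl$a, depl$a), delta_m = c(ctrl$d, depl$d))
  out
}

#' Complete transcription shutoff
#'
#' Models a complete transcription block (e.g. rapid Pol II depletion) by
#' inflating `Kv` so the production rate collapses to ~0 at t = 0.
#' Released X drains from the nucleus at `alpha_x`, cytoplasmic X shuttles
#' back and accumulates in the transcription-factor pool until nearly all
#' X is nuclear; mRNA settles at a lower plateau.
#'
#' @param p An `rs_params` object.
#' @param horizon Simulation horizon (min).
#' @param kv_blowup Factor applied to `Kv` (default 1e12).
#' @param dt Output grid spacing (min).
#' @return An `rs_trajectory` tibble (initial state = pre-shutoff steady
#'   state; parameters have the inflated `Kv`).
#' @export
transcription_shutoff <- function(p, horizon = 5000, kv_blowup = 1e12,
                                  dt = 2) {
  p <- validate_params(p)
  init <- rs_steady_state(p)$state
  p_off <- update_params(p, Kv = p$Kv * kv_blowup)
  rs_simulate(p_off, init = init, times = seq(0, horizon, by = dt))
}

#' Recovery time after a production-rate step
#'
#' Halves (or scales by `k0_factor`) the production prefactor at t = 0
#' from the steady state and measures how long the cytoplasmic (or
#' nuclear) mRNA fold takes to recover. The fold curve is shifted and
#' normalized so its pre-perturbation value is 1 and its minimum is 0; the
#' recovery time is the first re-crossing of `threshold` after the
#' minimum.
#'
#' @param p An `rs_params` object.
#' @param k0_factor Multiplier on `k0`, in (0, 1).
#' @param threshold Recovery threshold on the normalized fold (default 0.9).
#' @param compartment `"cytoplasmic"` or `"nuclear"`.
#' @param horizon,dt Simulation grid (min).
#' @return A list: `time` (min; `Inf` with `recovered = FALSE` if the
#'   threshold is not reached within the horizon), `recovered`,
#'   `trajectory` (tibble with `time`, `fold`, `norm_fold`).
#' @export
recovery_time <- function(p, k0_factor = 0.5, threshold = 0.9,
                          compartment = c("cytoplasmic", "nuclear"),
                          horizon = 5000, dt = 1) {
  if (k0_factor <= 0 || k0_factor >= 1) stop("'k0_factor' must be in (0, 1)")
  compartment <- match.arg(compartment)
  p <- validate_params(p)
  init <- rs_steady_state(p)$state
  p_step <- update_params(p, k0 = k0_factor * p$k0)
  tr <- rs_simulate(p_step, init = init, times = seq(0, horizon, by = dt))
  col <- if (compartment == "cytoplasmic") "Nmc" else "Nmn"
  base <- init[[col]]
  fold <- tr[[col]] / base
  fmin <- min(fold)
  if (1 - fmin < 1e-12) {
    return(list(time = 0, recovered = TRUE,
                trajectory = tibble::tibble(time = tr$time, fold = fold,
                                            norm_fold = fold)))
  }
  norm <- (fold - fmin) / (1 - fmin)
  imin <- which.min(fold)
  t_rec <- cross_time(tr$time[imin:length(norm)], norm[imin:length(norm)],
                      threshold, below = FALSE)
  recovered <- !is.na(t_rec)
  list(time = if (recovered) t_rec else Inf, recovered = recovered,
       trajectory = tibble::tibble(time = tr$time, fold = fold,
                                   norm_fold = norm))
}

#' Host-shutoff (viral infection) time course
#'
#' Runs the PABPC1 variant (with the export constant `alpha_m` scaled 20x
#' relative to the basic set, the host-shutoff preset) to its steady
#' state, then multiplies the degradation constant `beta_m` by
#' `beta_m_factor` at t = 0 and integrates. After the step the per-mRNA
#' degradation rate rises, the production rate falls, total mRNA falls,
#' nuclear P (`NPn + Nmn`) rises and cytoplasmic P (`NPc + Nmc`) falls.
#'
#' @param vp An `rs_variant` of kind `"pabpc1"`; default applies the
#'   20x `alpha_m` preset to the basic parameters.
#' @param beta_m_factor Degradation step factor (default 10).
#' @param horizon,dt Simulation grid (min).
#' @return A tibble with `time`, the variant state columns, `kn`,
#'   `delta_m`, `nuclear_P`, `cytoplasmic_P`, `total_mrna`, and fold
#'   columns relative to t = 0.
#' @export
viral_infection_timecourse <- function(vp = NULL, beta_m_factor = 10,
                                       horizon = 3000, dt = 2) {
  if (beta_m_factor <= 0) stop("'beta_m_factor' must be positive")
  if (is.null(vp)) {
    p0 <- rs_params()
    vp <- rs_variant("pabpc1", update_params(p0, alpha_m = 20 * p0$alpha_m))
  }
  if (vp$kind != "pabpc1") stop("'vp' must be a pabpc1 variant")
  init <- variant_relax(vp)
  vp_step <- vp
  vp_step$params <- update_params(vp$params,
                                  beta_m = beta_m_factor * vp$params$beta_m)
  tr <- variant_simulate(vp_step, init = init,
                         times = seq(0, horizon, by = dt))
  p <- vp_step$params
  tr$kn <- vapply(seq_len(nrow(tr)), function(i) {
    variant_production(vp_step, unlist(tr[i, variant_state_names("pabpc1")]))
  }, numeric(1))
  tr$delta_m <- p$beta_m * tr$NXc / p$Vc
  tr$nuclear_P <- tr$NPn + tr$Nmn
  tr$cytoplasmic_P <- tr$NPc + tr$Nmc
  tr$total_mrna <- tr$Nmn + tr$Nmc
  base_dm <- vp$params$beta_m * init[["NXc"]] / vp$params$Vc
  base_kn <- variant_production(vp, init)
  tr$kn_fold <- tr$kn / base_kn
  tr$delta_m_fold <- tr$delta_m / base_dm
  tr$mrna_fold <- tr$total_mrna / (init[["Nmn"]] + init[["Nmc"]])
  tr$nuclear_P_fold <- tr$nuclear_P / (init[["NPn"]] + init[["Nmn"]])
  tr$cytoplasmic_P_fold <- tr$cytoplasmic_P / (init[["NPc"]] + init[["Nmc"]])
  tr
}

#' Two-group depletion time course
#'
#' Two independent RS systems (two groups of genes with their own X and
#' Y). At t = 0 the cytoplasmic X of group 1 is reduced to `xc_factor` of
#' its steady value; group 2 shares no state and stays exactly constant.
#'
#' @param vp An `rs_variant` of kind `"two_group"`; default uses the basic
#'   parameters for both groups.
#' @param xc_factor Remaining fraction of group-1 cytoplasmic X.
#' @param horizon,dt Simulation grid (min).
#' @return A tibble with `time`, per-group total mRNA folds
#'   (`mrna_fold_1`, `mrna_fold_2`) and the combined fold `total_fold`.
#' @export
two_group_timecourse <- function(vp = NULL, xc_factor = 0.1,
                                 horizon = 600, dt = 1) {
  if (is.null(vp)) vp <- rs_variant("two_group", rs_params())
  if (vp$kind != "two_group") stop("'vp' must be a two_group variant")
  s1 <- rs_steady_state(vp$params)$state
  s2 <- rs_steady_state(vp$params2)$state
  removed <- (1 - xc_factor) * s1[["NXc"]]
  vp_post <- vp
  vp_post$params <- update_params(vp$params, NXt = vp$params$NXt - removed)
  init <- setNames(c(s1, s2), variant_state_names("two_group"))
  init[["NXc_1"]] <- s1[["NXc"]] - removed
  tr <- variant_simulate(vp_post, init = init,
                         times = seq(0, horizon, by = dt))
  m1_bf <- s1[["Nmn"]] + s1[["Nmc"]]
  m2_bf <- s2[["Nmn"]] + s2[["Nmc"]]
  tr$mrna_fold_1 <- (tr$Nmn_1 + tr$Nmc_1) / m1_bf
  tr$mrna_fold_2 <- (tr$Nmn_2 + tr$Nmc_2) / m2_bf
  tr$total_fold <- (tr$Nmn_1 + tr$Nmc_1 + tr$Nmn_2 + tr$Nmc_2) /
    (m1_bf + m2_bf)
  tr
}
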