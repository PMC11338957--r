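#' Model variants
#'
#' The RS mechanism admits several modifications that probe which of its
#' ingredients are essential for buffering. Each variant is selected by a
#' kind string (case-insensitive):
#'
#' * `"nonessential_x"` -- transcription proceeds without the X
#'   transcription factor (coarse prefactors `k1 < k2`); buffering breaks.
#' * `"shuttling_y"` -- Y is exported to the cytoplasm and shuttles back
#'   at `beta_y`; buffering holds.
#' * `"exosome"` -- a nuclear decay/transcription factor Z degrades nuclear
#'   mRNA at `alpha_d` and converts at `alpha_z`; buffering holds.
#' * `"dropoff"` -- a constant premature-termination probability `delta`
#'   scales the mRNA yield (but not the release of X and Y); both
#'   concentrations scale by `1 - delta`.
#' * `"imprinting"` -- released X binds nascent mRNA and is co-exported;
#'   buffering holds.
#' * `"pabpc1"` -- a third protein P (PABPC1) is released on mRNA decay,
#'   shuttles nuclear at `beta_p` and represses transcription with MM
#'   constant `Kp`; used for the host-shutoff protocol. Numeric only.
#' * `"two_group"` -- two fully independent RS systems. Numeric only.
#'
#' @name rs_variants
NULL

variant_kinds <- c("nonessential_x", "shuttling_y", "exosome", "dropoff",
                   "imprinting", "pabpc1", "two_group")

#' Construct a variant model
#'
#' @param kind One of the variant kind strings (see [rs_variants]).
#' @param params Base `rs_params` set (for `"two_group"`, the group-1 set).
#' @param ... Variant extras: `k1`, `k2` (nonessential_x); `beta_y`
#'   (shuttling_y); `alpha_z`, `alpha_d`, `Kz`, `NZt` (exosome); `delta`
#'   (dropoff); `beta_p`, `Kp`, `NPt` (pabpc1); `params2` (two_group).
#' @return A list of class `rs_variant` with `kind`, `params`, and extras.
#' @export
rs_variant <- function(kind, params = rs_params(), ...) {
  kind <- tolower(kind)
  if (!kind %in% variant_kinds) {
    stop("unknown variant kind '", kind, "'; must be one of: ",
         paste(variant_kinds, collapse = ", "), call. = FALSE)
  }
  params <- validate_params(params)
  extras <- list(...)
  defaults <- switch(kind,
    nonessential_x = list(k1 = 50, k2 = 500),
    shuttling_y    = list(beta_y = 0.05),
    exosome        = list(alpha_z = 0.5, alpha_d = 1e-5, Kz = 100, NZt = 1e4),
    dropoff        = list(delta = 0.2),
    pabpc1         = list(beta_p = 0.05, Kp = 2e4, NPt = 6e4),
    two_group      = list(params2 = params),
    list())
  unknown <- setdiff(names(extras), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown extra parameter(s) for variant '", kind, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  extras <- utils::modifyList(defaults, extras)
  if (kind == "dropoff" &&
      (extras$delta < 0 || extras$delta >= 1)) {
    stop("'delta' must lie in [0, 1)", call. = FALSE)
  }
  if (kind == "two_group") extras$params2 <- validate_params(extras$params2)
  pos <- setdiff(names(extras), c("params2", "delta"))
  for (nm in pos) {
    if (!is.numeric(extras[[nm]]) || extras[[nm]] <= 0) {
      stop("variant extra '", nm, "' must be positive", call. = FALSE)
    }
  }
  structure(c(list(kind = kind, params = params), extras),
            class = "rs_variant")
}

variant_state_names <- function(kind) {
  switch(kind,
    nonessential_x = rs_state_names,
    shuttling_y    = c(rs_state_names, "NYc"),
    exosome        = c(rs_state_names, "NZn", "NZp"),
    dropoff        = rs_state_names,
    imprinting     = rs_state_names,
    pabpc1         = c(rs_state_names, "NPn", "NPc"),
    two_group      = c(paste0(rs_state_names, "_1"), paste0(rs_state_names, "_2")))
}

#' Production rate of a variant
#'
#' @param vp An `rs_variant` object.
#' @param state Variant state vector (see [variant_state_names] layout).
#' @return Production rate(s) in molecules/min. For `"nonessential_x"` a
#'   named vector `c(kn0, knp)`; for `"two_group"` a vector per group.
#' @keywords internal
variant_production <- function(vp, state) {
  p <- vp$params
  switch(vp$kind,
    nonessential_x = {
      cXp <- state[["NXp"]] / p$Vn
      c(kn0 = vp$k1 * p$Kx / (p$Kx + cXp),
        knp = vp$k2 * cXp / (p$Kx + cXp))
    },
    exosome = {
      cZp <- state[["NZp"]] / p$Vn
      production_rate(state, p) * cZp / (cZp + vp$Kz)
    },
    pabpc1 = {
      cPn <- state[["NPn"]] / p$Vn
      production_rate(state, p) * vp$Kp / (cPn + vp$Kp)
    },
    production_rate(state, p))
}

#' Time derivatives of a variant model
#'
#' Implements the variant ODE systems. Per-kind conservation laws (total
#' X, Y; Z for the exosome; P for pabpc1; per-group totals for two_group)
#' hold identically. For `"pabpc1"` the mRNA-bound P pools are identified
#' with the mRNA pools (tight binding), so only the free pools `NPn`,
#' `NPc` are explicit state.
#'
#' @param vp An `rs_variant` object.
#' @param state Variant state vector.
#' @return Named derivative vector matching the state layout.
#' @export
variant_derivatives <- function(vp, state) {
  p <- vp$params
  nms <- variant_state_names(vp$kind)
  if (!all(nms %in% names(state)) || length(state) != length(nms)) {
    stop("state dimension/names do not match variant '", vp$kind, "'",
         call. = FALSE)
  }
  switch(vp$kind,
    nonessential_x = {
      kk <- variant_production(vp, state)
      kn <- sum(kk); knp <- kk[["knp"]]
      export <- p$alpha_m * state[["NYn"]] / p$Vn * state[["Nmn"]]
      degr   <- p$beta_m * state[["NXc"]] / p$Vc * state[["Nmc"]]
      c(Nmn = kn - export, Nmc = export - degr,
        NXn = knp - p$alpha_x * state[["NXn"]],
        NXc = p$alpha_x * state[["NXn"]] - p$beta_x * state[["NXc"]],
        NXp = p$beta_x * state[["NXc"]] - knp,
        NYn = kn - p$alpha_y * state[["NYn"]],
        NYp = p$alpha_y * state[["NYn"]] - kn)
    },
    shuttling_y = {
      kn <- production_rate(state, p)
      core <- rs_derivatives(state[rs_state_names], p, kn = kn)
      core[["NYp"]] <- vp$beta_y * state[["NYc"]] - kn
      c(core,
        NYc = p$alpha_y * state[["NYn"]] - vp$beta_y * state[["NYc"]])
    },
    exosome = {
      kn <- variant_production(vp, state)
      export <- p$alpha_m * state[["NYn"]] / p$Vn * state[["Nmn"]]
      ndeg   <- vp$alpha_d * state[["NZn"]] / p$Vn * state[["Nmn"]]
      degr   <- p$beta_m * state[["NXc"]] / p$Vc * state[["Nmc"]]
      c(Nmn = kn - export - ndeg, Nmc = export - degr,
        NXn = kn - p$alpha_x * state[["NXn"]],
        NXc = p$alpha_x * state[["NXn"]] - p$beta_x * state[["NXc"]],
        NXp = p$beta_x * state[["NXc"]] - kn,
        NYn = kn - p$alpha_y * state[["NYn"]],
        NYp = p$alpha_y * state[["NYn"]] - kn,
        NZn = kn - vp$alpha_z * state[["NZn"]],
        NZp = vp$alpha_z * state[["NZn"]] - kn)
    },
    dropoff = {
      kn <- production_rate(state, p)
      core <- rs_derivatives(state, p, kn = kn)
      export <- p$alpha_m * state[["NYn"]] / p$Vn * state[["Nmn"]]
      core[["Nmn"]] <- (1 - vp$delta) * kn - export
      core[["Nmc"]] <- export -
        p$beta_m * state[["NXc"]] / p$Vc * state[["Nmc"]]
      core
    },
    imprinting = {
      kn <- production_rate(state, p)
      export <- p$alpha_m * state[["NYn"]] / p$Vn * state[["Nmn"]]
      degr   <- p$beta_m * state[["NXc"]] / p$Vc * state[["Nmc"]]
      c(Nmn = kn - export, Nmc = export - degr,
        NXn = kn - export,
        NXc = export - p$beta_x * state[["NXc"]],
        NXp = p$beta_x * state[["NXc"]] - kn,
        NYn = kn - p$alpha_y * state[["NYn"]],
        NYp = p$alpha_y * state[["NYn"]] - kn)
    },
    pabpc1 = {
      kn <- variant_production(vp, state)
      core <- rs_derivatives(state[rs_state_names], p, kn = kn)
      degr <- p$beta_m * state[["NXc"]] / p$Vc * state[["Nmc"]]
      c(core,
        NPn = vp$beta_p * state[["NPc"]] - kn,
        NPc = degr - vp$beta_p * state[["NPc"]])
    },
    two_group = {
      s1 <- setNames(state[paste0(rs_state_names, "_1")], rs_state_names)
      s2 <- setNames(state[paste0(rs_state_names, "_2")], rs_state_names)
      d1 <- rs_derivatives(s1, vp$params)
      d2 <- rs_derivatives(s2, vp$params2)
      setNames(c(d1, d2), variant_state_names("two_group"))
    })
}

# Default (steady-ish) initial state per variant, used to seed relaxation.
variant_default_init <- function(vp) {
  p <- vp$params
  switch(vp$kind,
    nonessential_x = {
      knp0 <- min(vp$k2, attr(validate_params(p), "kn_max")) / 2
      c(Nmn = p$alpha_y / p$alpha_m * p$Vn, Nmc = p$beta_x / p$beta_m * p$Vc,
        NXn = knp0 / p$alpha_x, NXc = knp0 / p$beta_x,
        NXp = max(p$NXt - knp0 * (1 / p$alpha_x + 1 / p$beta_x), p$NXt / 100),
        NYn = 100, NYp = max(p$NYt - 100, 1))
    },
    shuttling_y = {
      # Y must be split within the conserved total NYt
      ss <- rs_steady_state(p)$state
      ss[["NYn"]] <- 0.1 * p$NYt
      ss[["NYp"]] <- 0.7 * p$NYt
      c(ss, NYc = 0.2 * p$NYt)
    },
    imprinting = {
      # released X tracks nuclear mRNA (identical dynamics), so the init
      # pins NXn = Nmn inside the conserved X budget
      Nmn <- p$alpha_y / p$alpha_m * p$Vn
      NXc <- 0.5 * (p$NXt - Nmn)
      rs_state(Nmn = Nmn, Nmc = p$beta_x / p$beta_m * p$Vc,
               NXn = Nmn, NXc = NXc, NXp = p$NXt - Nmn - NXc,
               NYn = 0.1 * p$NYt, NYp = 0.9 * p$NYt)
    },
    exosome = {
      ss <- rs_steady_state(p)$state
      kn <- rs_steady_state(p)$kn
      c(ss, NZn = min(kn / vp$alpha_z, vp$NZt / 2),
        NZp = max(vp$NZt - min(kn / vp$alpha_z, vp$NZt / 2), 1))
    },
    pabpc1 = {
      ss <- rs_steady_state(p)$state
      bound <- ss[["Nmn"]] + ss[["Nmc"]]
      free <- max(vp$NPt - bound, 1)
      c(ss, NPn = free / 2, NPc = free / 2)
    },
    two_group = {
      s1 <- rs_steady_state(vp$params)$state
      s2 <- rs_steady_state(vp$params2)$state
      setNames(c(s1, s2), variant_state_names("two_group"))
    },
    rs_steady_state(p)$state[variant_state_names(vp$kind)])
}

#' Simulate a variant model
#'
#' @param vp An `rs_variant` object.
#' @param init Initial state; default seeds a near-steady configuration.
#' @param times Strictly increasing time grid (min).
#' @param rtol,atol Solver tolerances.
#' @return A tibble with `time` and the variant state columns.
#' @export
variant_simulate <- function(vp, init = NULL, times = seq(0, 1000, by = 5),
                             rtol = 1e-8, atol = 1e-10) {
  nms <- variant_state_names(vp$kind)
  if (is.null(init)) init <- variant_default_init(vp)
  y0 <- setNames(as.numeric(init[nms]), nms)
  rhs <- function(t, y, parms) list(unname(variant_derivatives(vp, y)))
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  out <- clip_negatives(unclass(out), nms)
  tibble::as_tibble(as.data.frame(out))
}

#' Relax a variant to its steady state numerically
#'
#' Long-horizon integration repeated until the maximum absolute derivative
#' falls below `tol`.
#'
#' @param vp An `rs_variant` object.
#' @param init Optional initial state.
#' @param t_block Length of each integration block (min).
#' @param tol Convergence tolerance on max |dstate/dt| (copies/min).
#' @param max_blocks Maximum number of blocks before giving up.
#' @return Named steady-state vector.
#' @export
variant_relax <- function(vp, init = NULL, t_block = 2e4, tol = 1e-7,
                          max_blocks = 30) {
  nms <- variant_state_names(vp$kind)
  state <- if (is.null(init)) variant_default_init(vp) else
    setNames(as.numeric(init[nms]), nms)
  for (b in seq_len(max_blocks)) {
    tr <- variant_simulate(vp, init = state, times = c(0, t_block / 2, t_block))
    state <- setNames(as.numeric(tr[nrow(tr), nms]), nms)
    if (max(abs(variant_derivatives(vp, state))) < tol) {
      return(state)
    }
  }
  stop("variant relaxation did not converge for kind '", vp$kind, "'",
       call. = FALSE)
}

#' Closed-form variant steady states
#'
#' Returns the printed steady-state solution where one exists
#' (`nonessential_x`, `shuttling_y`, `exosome`, `dropoff`, `imprinting`);
#' for `pabpc1` and `two_group` the result is flagged `numeric_only = TRUE`
#' and obtained by [variant_relax()].
#'
#' For the exosome variant, nuclear degradation removes a fraction
#' `alpha_d*alpha_y / (alpha_m*alpha_z + alpha_d*alpha_y)` of produced
#' mRNA before export, so the cytoplasmic pool carries the complementary
#' factor relative to the core model.
#'
#' @param vp An `rs_variant` object.
#' @return A list with `kind`, `numeric_only`, `kn` (self-consistent
#'   production rate where defined), `state` (named steady copy numbers),
#'   and concentrations `cmn`, `cmc`.
#' @export
variant_steady_state <- function(vp) {
  p <- vp$params
  kind <- vp$kind
  if (kind %in% c("pabpc1", "two_group")) {
    state <- variant_relax(vp)
    Vn <- p$Vn; Vc <- p$Vc
    cmn <- if (kind == "two_group") state[["Nmn_1"]] / Vn else state[["Nmn"]] / Vn
    cmc <- if (kind == "two_group") state[["Nmc_1"]] / Vc else state[["Nmc"]] / Vc
    return(list(kind = kind, numeric_only = TRUE, kn = NA_real_,
                state = state, cmn = cmn, cmc = cmc))
  }
  out <- switch(kind,
    nonessential_x = {
      # knp = k2 cXp/(Kx+cXp) with cXp from X conservation: bisection.
      budget <- 1 / p$alpha_x + 1 / p$beta_x
      g <- function(knp) {
        NXp <- p$NXt - knp * budget
        if (NXp <= 0) return(knp)
        cXp <- NXp / p$Vn
        knp - vp$k2 * cXp / (p$Kx + cXp)
      }
      hi <- min(vp$k2, p$NXt / budget) * (1 - 1e-12)
      knp <- stats::uniroot(g, c(0, hi), tol = 1e-13 * hi)$root
      NXp <- p$NXt - knp * budget
      cXp <- NXp / p$Vn
      kn0 <- vp$k1 * p$Kx / (p$Kx + cXp)
      kn <- kn0 + knp
      cmc <- p$beta_x / p$beta_m *
        (vp$k1 * p$Kx * p$Vn + vp$k2 * NXp) / (vp$k2 * NXp)
      cmn <- p$alpha_y / p$alpha_m
      NYn <- kn / p$alpha_y
      st <- c(Nmn = cmn * p$Vn, Nmc = cmc * p$Vc,
              NXn = knp / p$alpha_x, NXc = knp / p$beta_x, NXp = NXp,
              NYn = NYn, NYp = p$NYt - NYn)
      list(kn = kn, state = st, cmn = cmn, cmc = cmc)
    },
    shuttling_y = {
      cmn <- p$alpha_y / p$alpha_m
      cmc <- p$beta_x / p$beta_m
      ybudget <- 1 / p$alpha_y + 1 / vp$beta_y
      g <- function(kn) {
        NXp <- p$NXt - kn * (1 / p$alpha_x + 1 / p$beta_x)
        NYp <- p$NYt - kn * ybudget
        if (NXp <= 0 || NYp <= 0) return(kn)
        kn - p$k0 * p$Vn / (p$Vn + p$Kv) * p$Km / (cmn + p$Km) *
          (NXp / p$Vn) / (NXp / p$Vn + p$Kx) *
          (NYp / p$Vn) / (NYp / p$Vn + p$Ky)
      }
      hi <- min(attr(p, "kn_max"), p$NYt / ybudget) * (1 - 1e-12)
      kn <- stats::uniroot(g, c(0, hi), tol = 1e-13 * hi)$root
      st <- c(Nmn = cmn * p$Vn, Nmc = cmc * p$Vc,
              NXn = kn / p$alpha_x, NXc = kn / p$beta_x,
              NXp = p$NXt - kn * (1 / p$alpha_x + 1 / p$beta_x),
              NYn = kn / p$alpha_y, NYp = p$NYt - kn * ybudget,
              NYc = kn / vp$beta_y)
      list(kn = kn, state = st, cmn = cmn, cmc = cmc)
    },
    exosome = {
      cmn <- vp$alpha_z * p$alpha_y /
        (p$alpha_m * vp$alpha_z + vp$alpha_d * p$alpha_y)
      export_frac <- p$alpha_m * vp$alpha_z /
        (p$alpha_m * vp$alpha_z + vp$alpha_d * p$alpha_y)
      cmc <- p$beta_x / p$beta_m * export_frac
      g <- function(kn) {
        NXp <- p$NXt - kn * (1 / p$alpha_x + 1 / p$beta_x)
        NYp <- p$NYt - kn / p$alpha_y
        NZp <- vp$NZt - kn / vp$alpha_z
        if (NXp <= 0 || NYp <= 0 || NZp <= 0) return(kn)
        kn - p$k0 * p$Vn / (p$Vn + p$Kv) * p$Km / (cmn + p$Km) *
          (NXp / p$Vn) / (NXp / p$Vn + p$Kx) *
          (NYp / p$Vn) / (NYp / p$Vn + p$Ky) *
          (NZp / p$Vn) / (NZp / p$Vn + vp$Kz)
      }
      hi <- min(attr(p, "kn_max"), p$alpha_y * p$NYt,
                vp$alpha_z * vp$NZt) * (1 - 1e-12)
      kn <- stats::uniroot(g, c(0, hi), tol = 1e-13 * hi)$root
      st <- c(Nmn = cmn * p$Vn, Nmc = cmc * p$Vc,
              NXn = kn / p$alpha_x, NXc = kn / p$beta_x,
              NXp = p$NXt - kn * (1 / p$alpha_x + 1 / p$beta_x),
              NYn = kn / p$alpha_y, NYp = p$NYt - kn / p$alpha_y,
              NZn = kn / vp$alpha_z, NZp = vp$NZt - kn / vp$alpha_z)
      list(kn = kn, state = st, cmn = cmn, cmc = cmc)
    },
    dropoff = {
      d <- vp$delta
      cmn <- (1 - d) * p$alpha_y / p$alpha_m
      cmc <- (1 - d) * p$beta_x / p$beta_m
      g <- function(kn) {
        NXp <- p$NXt - kn * (1 / p$alpha_x + 1 / p$beta_x)
        NYp <- p$NYt - kn / p$alpha_y
        if (NXp <= 0 || NYp <= 0) return(kn)
        kn - p$k0 * p$Vn / (p$Vn + p$Kv) * p$Km / (cmn + p$Km) *
          (NXp / p$Vn) / (NXp / p$Vn + p$Kx) *
          (NYp / p$Vn) / (NYp / p$Vn + p$Ky)
      }
      hi <- min(attr(p, "kn_max"), p$alpha_y * p$NYt) * (1 - 1e-12)
      kn <- stats::uniroot(g, c(0, hi), tol = 1e-13 * hi)$root
      st <- c(Nmn = cmn * p$Vn, Nmc = cmc * p$Vc,
              NXn = kn / p$alpha_x, NXc = kn / p$beta_x,
              NXp = p$NXt - kn * (1 / p$alpha_x + 1 / p$beta_x),
              NYn = kn / p$alpha_y, NYp = p$NYt - kn / p$alpha_y)
      list(kn = kn, state = st, cmn = cmn, cmc = cmc)
    },
    imprinting = {
      cmn <- p$alpha_y / p$alpha_m
      cmc <- p$beta_x / p$beta_m
      Nmn <- cmn * p$Vn
      g <- function(kn) {
        NXp <- p$NXt - Nmn - kn / p$beta_x
        NYp <- p$NYt - kn / p$alpha_y
        if (NXp <= 0 || NYp <= 0) return(kn)
        kn - p$k0 * p$Vn / (p$Vn + p$Kv) * p$Km / (cmn + p$Km) *
          (NXp / p$Vn) / (NXp / p$Vn + p$Kx) *
          (NYp / p$Vn) / (NYp / p$Vn + p$Ky)
      }
      hi <- min((p$NXt - Nmn) * p$beta_x, p$alpha_y * p$NYt) * (1 - 1e-12)
      kn <- stats::uniroot(g, c(0, hi), tol = 1e-13 * hi)$root
      st <- c(Nmn = Nmn, Nmc = cmc * p$Vc,
              NXn = Nmn, NXc = kn / p$beta_x,
              NXp = p$NXt - Nmn - kn / p$beta_x,
              NYn = kn / p$alpha_y, NYp = p$NYt - kn / p$alpha_y)
      list(kn = kn, state = st, cmn = cmn, cmc = cmc)
    })
  c(list(kind = kind, numeric_only = FALSE), out)
}

#' Steady mRNA concentration of the feedback-only null models
#'
#' Two single-species null models that lack the releasing-shuttling
#' mechanism: positive feedback of mRNA on its own degradation
#' (`dcm/dt = kn - beta_m cm^2`, steady `cm = sqrt(kn/beta_m)`), and
#' negative feedback of mRNA on its own production
#' (`dcm/dt = a/(cm + b) - beta_m cm`, steady state the positive root of
#' `beta_m cm^2 + beta_m b cm - a = 0`). In both, the steady concentration
#' depends on the production parameters -- no buffering.
#'
#' @param kind `"positive"` or `"negative"`.
#' @param kn Production rate (positive model).
#' @param a,b Production parameters (negative model).
#' @param beta_m Degradation constant.
#' @return Steady mRNA concentration.
#' @export
feedback_steady_state <- function(kind = c("positive", "negative"),
                                  kn = NULL, a = NULL, b = NULL, beta_m) {
  kind <- match.arg(kind)
  if (beta_m <= 0) stop("'beta_m' must be positive")
  if (kind == "positive") {
    if (is.null(kn) || kn <= 0) stop("'kn' must be positive")
    sqrt(kn / beta_m)
  } else {
    if (is.null(a) || is.null(b) || a <= 0 || b <= 0) {
      stop("'a' and 'b' must be positive")
    }
    (-beta_m * b + sqrt((beta_m * b)^2 + 4 * beta_m * a)) / (2 * beta_m)
  }
}
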