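#' @importFrom stats setNames
NULL

rs_state_names <- c("Nmn", "Nmc", "NXn", "NXc", "NXp", "NYn", "NYp")

#' Construct an RS model state
#'
#' A state holds the seven molecular copy numbers of the model: the nuclear
#' and cytoplasmic mRNA pools (`Nmn`, `Nmc`), the three states of the
#' degradation factor X (released `NXn`, cytoplasmic decay-factor `NXc`,
#' nuclear transcription-factor `NXp`) and the two states of the export
#' factor Y (export-factor `NYn`, transcription-factor `NYp`).
#'
#' @param Nmn,Nmc,NXn,NXc,NXp,NYn,NYp Non-negative copy numbers.
#' @return A named numeric vector of length 7 (class `rs_state`).
#' @export
rs_state <- function(Nmn, Nmc, NXn, NXc, NXp, NYn, NYp) {
  s <- c(Nmn = Nmn, Nmc = Nmc, NXn = NXn, NXc = NXc, NXp = NXp,
         NYn = NYn, NYp = NYp)
  if (anyNA(s) || any(!is.finite(s))) stop("state values must be finite")
  if (any(s < 0)) stop("copy numbers must be non-negative")
  structure(s, class = c("rs_state", "numeric"))
}

#' Nuclear/cytoplasmic concentrations of a state
#'
#' @param state A state vector (named, with the seven RS components).
#' @param p An `rs_params` object supplying `Vn` and `Vc`.
#' @return Named vector `cmn`, `cmc`, `cXp`, `cYp` in fL^-1.
#' @export
rs_concentrations <- function(state, p) {
  c(cmn = unname(state[["Nmn"]]) / p$Vn,
    cmc = unname(state[["Nmc"]]) / p$Vc,
    cXp = unname(state[["NXp"]]) / p$Vn,
    cYp = unname(state[["NYp"]]) / p$Vn)
}

#' mRNA production rate
#'
#' The production law is a product of four Michaelis-Menten factors and a
#' constant prefactor:
#' `kn = k0 * Vn/(Vn+Kv) * Km/(cmn+Km) * cXp/(cXp+Kx) * cYp/(cYp+Ky)`.
#' The first factor models limiting Pol II through the nuclear volume, the
#' second the negative feedback of nuclear mRNA on transcription, and the
#' last two the promoter occupancy of the transcription-factor states of
#' X and Y.
#'
#' @param state A state vector.
#' @param p An `rs_params` object.
#' @param volume_factor Optional replacement for the `Vn/(Vn+Kv)` factor
#'   (used by alternative volume-scaling laws); `NULL` keeps the MM form.
#' @return Production rate in molecules/min, in `[0, k0)`.
#' @export
production_rate <- function(state, p, volume_factor = NULL) {
  cc <- rs_concentrations(state, p)
  vf <- if (is.null(volume_factor)) p$Vn / (p$Vn + p$Kv) else volume_factor
  p$k0 * vf *
    (p$Km / (cc[["cmn"]] + p$Km)) *
    (cc[["cXp"]] / (cc[["cXp"]] + p$Kx)) *
    (cc[["cYp"]] / (cc[["cYp"]] + p$Ky))
}

#' Per-mRNA degradation rate
#'
#' `delta_m = beta_m * NXc / Vc`; the mRNA lifetime is `1/delta_m`.
#'
#' @inheritParams production_rate
#' @return Degradation rate per mRNA (1/min).
#' @export
degradation_rate_per_mrna <- function(state, p) {
  p$beta_m * unname(state[["NXc"]]) / p$Vc
}

#' Time derivatives of the RS model
#'
#' The seven coupled ODEs of the core model. X released at initiation
#' (rate `kn`) exits the nucleus at `alpha_x`, degrades cytoplasmic mRNA
#' proportionally to its concentration, and shuttles back at `beta_x`;
#' Y released at initiation exports nuclear mRNA and reverts at `alpha_y`.
#' The X-component and Y-component derivative sums vanish identically
#' (conservation of total X and Y).
#'
#' @inheritParams production_rate
#' @param kn Optional externally supplied production rate; default computes
#'   it from [production_rate()].
#' @return Named derivative vector (copies/min), names as the state.
#' @export
rs_derivatives <- function(state, p, kn = NULL) {
  if (is.null(kn)) kn <- production_rate(state, p)
  export <- p$alpha_m * state[["NYn"]] / p$Vn * state[["Nmn"]]
  degr   <- p$beta_m * state[["NXc"]] / p$Vc * state[["Nmc"]]
  x_out  <- p$alpha_x * state[["NXn"]]
  x_back <- p$beta_x * state[["NXc"]]
  y_back <- p$alpha_y * state[["NYn"]]
  c(Nmn = kn - export,
    Nmc = export - degr,
    NXn = kn - x_out,
    NXc = x_out - x_back,
    NXp = x_back - kn,
    NYn = kn - y_back,
    NYp = y_back - kn)
}

# Shared post-processing for deSolve output: negative-copy clipping and
# conservation checks. Values below -neg_tol are an integration failure;
# round-off negatives are clipped to zero with a warning.
clip_negatives <- function(mat, state_cols, neg_tol = 1e-9) {
  vals <- mat[, state_cols, drop = FALSE]
  if (any(vals < -neg_tol)) {
    worst <- min(vals)
    stop("integration produced negative copy numbers (min = ",
         format(worst), "); reduce tolerances or check parameters",
         call. = FALSE)
  }
  if (any(vals < 0)) {
    warning("clipped ", sum(vals < 0),
            " slightly negative copy number(s) to zero (round-off)",
            call. = FALSE)
    vals[vals < 0] <- 0
    mat[, state_cols] <- vals
  }
  mat
}

#' Simulate the RS model
#'
#' Integrates the seven ODEs with a stiff-capable solver (deSolve `lsoda`)
#' and returns a trajectory with the derived production and per-mRNA
#' degradation rate at every time point.
#'
#' @param p An `rs_params` object.
#' @param init Initial state (named vector with the seven components);
#'   default is the model steady state.
#' @param times Strictly increasing time grid (min).
#' @param rtol,atol Solver tolerances (relative; absolute in copies).
#' @param method deSolve integration method.
#' @return A tibble of class `rs_trajectory` with columns `time`, the seven
#'   copy numbers, `kn` and `delta_m`; the parameter set is attached as
#'   attribute `params`.
#' @export
#' @examples
#' p <- rs_params()
#' tr <- rs_simulate(p, times = seq(0, 60, by = 5))
#' tr$kn[1]
rs_simulate <- function(p, init = NULL, times = seq(0, 500, by = 1),
                        rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  p <- validate_params(p)
  if (is.null(init)) init <- rs_steady_state(p)$state
  if (is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing")
  }
  y0 <- setNames(as.numeric(init[rs_state_names]), rs_state_names)
  if (any(y0 < 0)) stop("initial state must be non-negative")
  rhs <- function(t, y, parms) list(unname(rs_derivatives(y, p)))
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed; last accepted time = ",
         max(out[, "time"], na.rm = TRUE), call. = FALSE)
  }
  out <- clip_negatives(unclass(out), rs_state_names)
  tr <- tibble::as_tibble(as.data.frame(out))
  tr$kn <- vapply(seq_len(nrow(tr)), function(i) {
    production_rate(unlist(tr[i, rs_state_names]), p)
  }, numeric(1))
  tr$delta_m <- p$beta_m * tr$NXc / p$Vc
  attr(tr, "params") <- p
  class(tr) <- c("rs_trajectory", class(tr))
  tr
}

#' Solve the RS steady state
#'
#' At steady state the nuclear and cytoplasmic mRNA concentrations are
#' pinned by rate-constant ratios (`cmn = alpha_y/alpha_m`,
#' `cmc = beta_x/beta_m`) independent of the production rate -- the
#' buffering property. The self-consistent production rate `kn*` solves
#' `kn = F(kn)` where `F` substitutes the conservation laws
#' `NXp = NXt - kn (1/alpha_x + 1/beta_x)` and `NYp = NYt - kn/alpha_y`
#' into the production law with `cmn` fixed at `alpha_y/alpha_m`. `F` is
#' strictly decreasing on the feasible bracket, so the fixed point is
#' unique and found by bisection.
#'
#' @param p An `rs_params` object.
#' @param rel_tol Relative bisection tolerance on `kn*`.
#' @return A list of class `rs_steady`: `state` (full seven-component
#'   steady state), `kn` (self-consistent production rate), `delta_m`
#'   (per-mRNA degradation rate), `converged`, and `residual`
#'   (max absolute RHS at the solution).
#' @export
#' @examples
#' ss <- rs_steady_state(rs_params())
#' ss$state[["Nmn"]] / rs_params()$Vn  # = alpha_y / alpha_m
rs_steady_state <- function(p, rel_tol = 1e-12) {
  p <- validate_params(p)
  knmax <- attr(p, "kn_max")
  hi <- min(knmax, p$alpha_y * p$NYt)
  if (hi <= 0) stop("infeasible parameters: kn_max <= 0", call. = FALSE)
  cmn <- p$alpha_y / p$alpha_m
  g <- function(kn) kn - steady_production(kn, p, cmn)
  lo <- 0
  if (g(hi * (1 - 1e-12)) < 0) {
    stop("steady-state bracket does not contain a sign change; ",
         "parameters infeasible", call. = FALSE)
  }
  hi_b <- hi * (1 - 1e-12)
  for (i in 1:200) {
    mid <- (lo + hi_b) / 2
    if (g(mid) > 0) hi_b <- mid else lo <- mid
    if ((hi_b - lo) <= rel_tol * max(mid, 1e-300)) break
  }
  kn <- (lo + hi_b) / 2
  state <- steady_state_from_kn(kn, p)
  deriv <- rs_derivatives(state, p)
  res <- max(abs(deriv))
  structure(list(state = state, kn = kn,
                 delta_m = degradation_rate_per_mrna(state, p),
                 converged = (hi_b - lo) <= rel_tol * max(kn, 1e-300),
                 residual = res),
            class = "rs_steady")
}

# Production law evaluated under the steady-state conservation closure.
steady_production <- function(kn, p, cmn, volume_factor = NULL) {
  NXp <- p$NXt - kn * (1 / p$alpha_x + 1 / p$beta_x)
  NYp <- p$NYt - kn / p$alpha_y
  if (NXp <= 0 || NYp <= 0) return(0)
  cXp <- NXp / p$Vn
  cYp <- NYp / p$Vn
  vf <- if (is.null(volume_factor)) p$Vn / (p$Vn + p$Kv) else volume_factor
  p$k0 * vf * (p$Km / (cmn + p$Km)) *
    (cXp / (cXp + p$Kx)) * (cYp / (cYp + p$Ky))
}

#' Steady-state copy numbers implied by a production rate
#'
#' The flux-balance relations: `NXn = kn/alpha_x`, `NXc = kn/beta_x`,
#' `NYn = kn/alpha_y`, with the transcription-factor pools from
#' conservation and the mRNA pools from the concentration ratios.
#'
#' @param kn Production rate (molecules/min).
#' @param p An `rs_params` object.
#' @return An `rs_state` vector.
#' @export
steady_state_from_kn <- function(kn, p) {
  rs_state(Nmn = p$alpha_y / p$alpha_m * p$Vn,
           Nmc = p$beta_x / p$beta_m * p$Vc,
           NXn = kn / p$alpha_x,
           NXc = kn / p$beta_x,
           NXp = max(p$NXt - kn / p$alpha_x - kn / p$beta_x, 0),
           NYn = kn / p$alpha_y,
           NYp = max(p$NYt - kn / p$alpha_y, 0))
}

#' @export
print.rs_steady <- function(x, ...) {
  cat("<rs_steady>  kn* =", signif(x$kn, 6), "molecules/min,",
      "delta_m* =", signif(x$delta_m, 6), "/min\n")
  print(signif(unclass(x$state), 6))
  cat("converged:", x$converged, " residual:", format(x$residual), "\n")
  invisible(x)
}

#' Tidy a steady-state solution
#' @param x An `rs_steady` object.
#' @param ... Unused.
#' @return A tibble with one row per molecular species.
#' @method tidy rs_steady
#' @export
tidy.rs_steady <- function(x, ...) {
  tibble::tibble(species = names(x$state),
                 copies = as.numeric(x$state))
}

#' One-row summary of a steady-state solution
#' @param x An `rs_steady` object.
#' @param ... Unused.
#' @return A tibble with `kn`, `delta_m`, `converged`, `residual`.
#' @method glance rs_steady
#' @export
glance.rs_steady <- function(x, ...) {
  tibble::tibble(kn = x$kn, delta_m = x$delta_m,
                 converged = x$converged, residual = x$residual)
}

#' Write / read a trajectory as CSV
#'
#' Canonical delimited format with columns
#' `time,Nmn,Nmc,NXn,NXc,NXp,NYn,NYp,kn,delta_m`.
#'
#' @param tr An `rs_trajectory` tibble.
#' @param path Output file path.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_trajectory <- function(tr, path) {
  cols <- c("time", rs_state_names, "kn", "delta_m")
  readr::write_csv(tr[, cols], path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time", rs_state_names, "kn", "delta_m")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0) {
    stop("trajectory file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tr
}
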