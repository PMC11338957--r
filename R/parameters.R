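#' Basic parameter set of the releasing-shuttling model
#'
#' Constructs the full parameter set of the RS model. Defaults are the
#' basic set obtained from fitting budding-yeast kinetic data (production
#' prefactor `k0`, the four Michaelis-Menten constants, the export/shuttle
#' rate constants, total copy numbers of the degradation factor X and the
#' export factor Y, and the nuclear and cytoplasmic volumes).
#'
#' Units are fixed package-wide: copy numbers (dimensionless), volumes in
#' fL, times in minutes, concentrations in fL^-1.
#'
#' @param k0 Maximal production prefactor (molecules/min).
#' @param Kx,Ky,Km MM constants for the nuclear concentrations of the
#'   transcription-factor states of X and Y and for the nuclear-mRNA
#'   negative feedback (fL^-1).
#' @param Kv MM constant for the nuclear volume, a proxy for limiting
#'   Pol II (fL).
#' @param alpha_m mRNA export rate constant (fL/min).
#' @param alpha_x Nuclear-exit rate of released X (1/min).
#' @param alpha_y Conversion rate of the export-factor state of Y back to
#'   its transcription-factor state (1/min).
#' @param beta_m mRNA degradation rate constant (fL/min).
#' @param beta_x Shuttling rate of cytoplasmic X back to the nucleus (1/min).
#' @param NXt,NYt Total copy numbers of proteins X and Y.
#' @param Vn,Vc Nuclear and cytoplasmic volumes (fL).
#'
#' @return An object of class `rs_params`: a named list of the 14 constants.
#' @seealso [validate_params()], [rs_steady_state()]
#' @export
#' @examples
#' p <- rs_params()
#' p$alpha_x
#' rs_params(Kv = 2 * rs_params()$Kv)  # halved Pol II concentration
rs_params <- function(k0 = 6000, Kx = 180.18, Ky = 100, Km = 5086.24,
                      Kv = 5.83, alpha_m = 3.28e-5, alpha_x = 0.10,
                      alpha_y = 0.52, beta_m = 9.92e-6, beta_x = 2.24e-3,
                      NXt = 2.30e5, NYt = 1.10e4, Vn = 2.80, Vc = 37.20) {
  p <- list(k0 = k0, Kx = Kx, Ky = Ky, Km = Km, Kv = Kv,
            alpha_m = alpha_m, alpha_x = alpha_x, alpha_y = alpha_y,
            beta_m = beta_m, beta_x = beta_x, NXt = NXt, NYt = NYt,
            Vn = Vn, Vc = Vc)
  p <- lapply(p, unname)
  class(p) <- "rs_params"
  validate_params(p)
}

#' Names of the RS model parameters
#' @return Character vector of the 14 parameter names.
#' @export
rs_param_names <- function() {
  c("k0", "Kx", "Ky", "Km", "Kv", "alpha_m", "alpha_x", "alpha_y",
    "beta_m", "beta_x", "NXt", "NYt", "Vn", "Vc")
}

#' Validate an RS parameter set
#'
#' Checks that every field is a finite, strictly positive scalar and
#' annotates the feasibility bound `kn_max = NXt / (1/alpha_x + 1/beta_x)`,
#' the largest steady-state production rate for which the nuclear
#' transcription-factor pool of X remains non-negative.
#'
#' @param p An `rs_params` object or a named list with the 14 fields.
#' @return `p` (classed, with attribute `kn_max`); errors on invalid fields.
#' @export
validate_params <- function(p) {
  nms <- rs_param_names()
  missing <- setdiff(nms, names(p))
  if (length(missing) > 0) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in nms) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("parameter '", nm, "' must be a finite positive scalar",
           call. = FALSE)
    }
  }
  p <- p[nms]
  class(p) <- "rs_params"
  attr(p, "kn_max") <- p$NXt / (1 / p$alpha_x + 1 / p$beta_x)
  p
}

#' @export
print.rs_params <- function(x, ...) {
  cat("<rs_params>  (copies, fL, minutes)\n")
  vals <- unlist(x[rs_param_names()])
  print(signif(vals, 6))
  cat("feasibility bound kn_max:", signif(kn_max(x), 6), "molecules/min\n")
  invisible(x)
}

#' Feasibility bound on the production rate
#'
#' @param p An `rs_params` object.
#' @return `NXt / (1/alpha_x + 1/beta_x)` (molecules/min).
#' @export
kn_max <- function(p) {
  p <- validate_params(p)
  attr(p, "kn_max")
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced, e.g.
#' `update_params(p, Kv = 2 * p$Kv)` for a Pol II depletion preset.
#'
#' @param p An `rs_params` object.
#' @param ... Named replacement values; names must be parameter fields.
#' @return A validated `rs_params` object.
#' @export
update_params <- function(p, ...) {
  repl <- list(...)
  unknown <- setdiff(names(repl), rs_param_names())
  if (length(unknown) > 0) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(repl)] <- repl
  validate_params(p)
}
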