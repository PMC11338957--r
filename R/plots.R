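#' Plot an RS trajectory
#'
#' Copy numbers (or fold changes, when present) of the molecular species
#' over time, one facet per species.
#'
#' @param object An `rs_trajectory` tibble.
#' @param species Columns to show; default the seven copy numbers.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rs_trajectory
#' @export
autoplot.rs_trajectory <- function(object,
                                   species = c("Nmn", "Nmc", "NXn", "NXc",
                                               "NXp", "NYn", "NYp"),
                                   ...) {
  long <- tidyr::pivot_longer(object[, c("time", species)],
                              -"time", names_to = "species",
                              values_to = "copies")
  long$species <- factor(long$species, levels = species)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$copies)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "copy number") +
    ggplot2::theme_minimal()
}

#' Plot a perturbation screen
#'
#' Fold change of a steady-state observable against the production-rate
#' fold, with the x = 1 buffering reference line.
#'
#' @param object An `rs_screen` object.
#' @param y Observable: `"cmc_fold"`, `"cmn_fold"`, or `"delta_m_fold"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rs_screen
#' @export
autoplot.rs_screen <- function(object, y = c("cmc_fold", "cmn_fold",
                                             "delta_m_fold"), ...) {
  y <- match.arg(y)
  gg <- ggplot2::ggplot(object$samples,
                        ggplot2::aes(.data$kn_fold, .data[[y]])) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "production-rate fold", y = y) +
    ggplot2::theme_minimal()
  if (y == "delta_m_fold") {
    gg + ggplot2::geom_abline(slope = 1, intercept = 0,
                              linetype = "dashed", colour = "blue")
  } else {
    gg + ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                             colour = "blue")
  }
}

#' Plot an acute-depletion experiment
#'
#' Total-mRNA and production-rate fold changes over time with the phase
#' boundaries marked.
#'
#' @param object An `rs_depletion` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rs_depletion
#' @export
autoplot.rs_depletion <- function(object, ...) {
  tr <- object$trajectory
  long <- tidyr::pivot_longer(tr[, c("time", "mrna_fold", "kn_fold")],
                              -"time", names_to = "series",
                              values_to = "fold")
  ph <- object$phases
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$fold,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(ph$Tacc, ph$T3),
                        linetype = "dotted") +
    ggplot2::labs(x = "time (min)", y = "fold change vs. pre-depletion") +
    ggplot2::theme_minimal()
}
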