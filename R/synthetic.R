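#' Basic parameter set
#'
#' Returns the basic parameter set (identical to the [rs_params()]
#' defaults): `k0 = 6000`/min, `Kx = 180.18`/fL, `Ky = 100`/fL,
#' `Km = 5086.24`/fL, `Kv = 5.83` fL, `alpha_m = 3.28e-5` fL/min,
#' `alpha_x = 0.10`/min, `alpha_y = 0.52`/min, `beta_m = 9.92e-6` fL/min,
#' `beta_x = 2.24e-3`/min, `NXt = 2.3e5`, `NYt = 1.1e4`, `Vn = 2.8` fL,
#' `Vc = 37.2` fL.
#'
#' @return An `rs_params` object.
#' @export
basic_parameters <- function() rs_params()

#' Noise specification for synthetic datasets
#'
#' @param poisson_counts Sample mRNA copy numbers from a Poisson
#'   distribution around the model prediction?
#' @param rate_cv CV of multiplicative Gaussian noise on rate-like series
#'   (default 0.05).
#' @param fold_cv Optional extra CV on fold series (default 0).
#' @param seed Integer seed.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(poisson_counts = TRUE, rate_cv = 0.05, fold_cv = 0,
                       seed = 1L) {
  if (rate_cv < 0 || fold_cv < 0) stop("CVs must be >= 0")
  structure(list(poisson_counts = isTRUE(poisson_counts),
                 rate_cv = rate_cv, fold_cv = fold_cv,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Synthetic depletion time-course dataset
#'
#' Simulates the acute cytoplasmic-X depletion protocol, samples total
#' mRNA copy numbers per time point (Poisson, if enabled), applies
#' multiplicative Gaussian noise to the production-rate series,
#' normalizes both at t = 0, and returns a fold-change dataset of the
#' same shape as the empirical depletion tables, together with the
#' generating ground truth.
#'
#' @param p Generating `rs_params` (default the basic set).
#' @param fdep Depleted fraction of cytoplasmic X (default 0.8).
#' @param times Time grid including 0 (default 0-300 min at 1-min steps).
#' @param noise A [noise_spec()]; `noise_spec(FALSE, 0)` for noiseless.
#' @return A list of class `rs_synth_timecourse`: `dataset` (tibble
#'   `time`, `total_fold`, `nascent_fold`), `truth` (the noiseless fold
#'   curves plus the generating trajectory and parameters).
#' @export
synth_depletion_dataset <- function(p = basic_parameters(), fdep = 0.8,
                                    times = seq(0, 300, by = 1),
                                    noise = noise_spec()) {
  if (!any(times == 0)) stop("'times' must include the reference t = 0")
  dep <- acute_depletion_timecourse(p, fdep = fdep, horizon = max(times),
                                    dt = min(diff(sort(unique(times)))))
  tr <- dep$trajectory
  idx <- match(times, tr$time)
  if (anyNA(idx)) stop("'times' must lie on the simulation grid")
  total_true <- tr$mrna_fold[idx]
  nascent_true <- tr$kn_fold[idx]
  set.seed(noise$seed)
  mrna_bf <- dep$steady_pre$state[["Nmn"]] + dep$steady_pre$state[["Nmc"]]
  total <- total_true
  if (noise$poisson_counts) {
    counts <- stats::rpois(length(total_true), total_true * mrna_bf)
    # re-normalize at t = 0 as the empirical tables are
    total <- counts / counts[which(times == 0)]
  }
  nascent <- mult_gauss(nascent_true, noise$rate_cv)
  nascent <- nascent / nascent[which(times == 0)]
  if (noise$fold_cv > 0) {
    total <- mult_gauss(total, noise$fold_cv)
    total <- total / total[which(times == 0)]
  }
  structure(list(
    dataset = tibble::tibble(time = times, total_fold = total,
                             nascent_fold = nascent),
    truth = list(params = p, fdep = fdep,
                 total_fold = total_true, nascent_fold = nascent_true,
                 trajectory = tr, phases = dep$phases, kn_bf = dep$kn_bf,
                 mrna_bf = mrna_bf, noise = noise)),
    class = "rs_synth_timecourse")
}

#' Synthetic perturbation-screen table
#'
#' Wraps [run_perturbation_screen()] (or [run_alpha_m_screen()] when
#' `alpha_m_screen = TRUE`) into a per-sample screen table with
#' scrambled-control records at the base parameters, emulating the
#' structure of the genome-wide perturbation tables. The recorded
#' signals are the concentration and production folds themselves, so
#' [read_screen_table()] recovers the generator's folds exactly.
#'
#' @param p Base `rs_params`.
#' @param cfg A [screen_config()].
#' @param n_controls Number of scrambled-control records (signals = 1).
#' @param alpha_m_screen Use the export-impairment screen protocol?
#' @return A list of class `rs_synth_screen`: `table` (per-sample tibble
#'   with columns `gene`, `nuclear`, `cytoplasmic`, `production`,
#'   `scrambled`) and `truth` (the underlying `rs_screen`).
#' @export
synth_screen_dataset <- function(p = basic_parameters(),
                                 cfg = screen_config(), n_controls = 10,
                                 alpha_m_screen = FALSE) {
  scr <- if (alpha_m_screen) run_alpha_m_screen(p, cfg) else
    run_perturbation_screen(p, cfg)
  s <- scr$samples
  genes <- sprintf("gene_%04d", s$sample)
  tab <- tibble::tibble(
    gene = c(genes, rep("scrambled", n_controls)),
    nuclear = c(s$cmn_fold, rep(1, n_controls)),
    cytoplasmic = c(s$cmc_fold, rep(1, n_controls)),
    production = c(s$kn_fold, rep(1, n_controls)),
    scrambled = c(rep(FALSE, nrow(s)), rep(TRUE, n_controls)))
  structure(list(table = tab, truth = scr), class = "rs_synth_screen")
}

#' Synthetic volume-scaling dataset
#'
#' Production-rate fold changes across cell volumes generated from the
#' Pol II-proxy MM law at a known `Kv`, with optional multiplicative
#' noise, plus model-derived degradation-rate folds for cross-checks.
#'
#' @param p Base `rs_params` (supplies the nuclear volume fraction and
#'   the reference volume).
#' @param Kv_true Generating MM constant (fL).
#' @param volumes Total cell volumes (fL); the reference is `Vn + Vc`
#'   of `p`.
#' @param noise A [noise_spec()]; `rate_cv` applies to the fold series.
#' @return A list of class `rs_synth_volume`: `dataset` (tibble `volume`,
#'   `kn_fold`, `delta_m_fold`, `mrna_fold`) and `truth`.
#' @export
synth_volume_dataset <- function(p = basic_parameters(), Kv_true = p$Kv,
                                 volumes = c(20, 40, 60, 80),
                                 noise = noise_spec(poisson_counts = FALSE,
                                                    rate_cv = 0)) {
  if (length(volumes) < 2) stop("need >= 2 volumes")
  v0 <- p$Vn + p$Vc
  ratio <- p$Vn / v0
  vn <- volumes * ratio
  vn0 <- v0 * ratio
  fc_true <- vn * (vn0 + Kv_true) / (vn0 * (vn + Kv_true))
  scan <- volume_scan(update_params(p, Kv = Kv_true), volumes = volumes,
                      scaling = "mm")
  set.seed(noise$seed)
  fc <- mult_gauss(fc_true, noise$rate_cv)
  structure(list(
    dataset = tibble::tibble(volume = volumes, kn_fold = fc,
                             delta_m_fold = scan$delta_m_fold,
                             mrna_fold = scan$mrna_fold),
    truth = list(Kv = Kv_true, kn_fold = fc_true, vn_ratio = ratio,
                 v0 = v0, noise = noise, scan = scan)),
    class = "rs_synth_volume")
}
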