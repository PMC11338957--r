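p_tbl <- rs_params()

test_that("noiseless screens return exactly unit concentration folds", {
  cfg <- screen_config(n_samples = 8, cv_kn_params = 0, cv_other = 0,
                       cv_totals = 0, mrna_noise = FALSE,
                       rate_noise_cv = 0, seed = 5)
  scr <- run_perturbation_screen(p_tbl, cfg)
  expect_true(all(abs(scr$samples$cmn_fold - 1) < 1e-12))
  expect_true(all(abs(scr$samples$cmc_fold - 1) < 1e-12))
  expect_true(all(abs(scr$samples$kn_fold - 1) < 1e-12))
  expect_identical(scr$summary$n_rejected, 0L)
})

test_that("screens are seed-deterministic and positive", {
  cfg <- screen_config(n_samples = 40, seed = 42)
  a <- run_perturbation_screen(p_tbl, cfg)
  b <- run_perturbation_screen(p_tbl, cfg)
  expect_identical(a$samples, b$samples)
  c2 <- run_perturbation_screen(p_tbl, screen_config(n_samples = 40,
                                                     seed = 43))
  expect_false(identical(a$samples$kn_fold, c2$samples$kn_fold))
  expect_true(all(as.matrix(a$samples[, -1]) > 0))
})

test_that("an isolated export impairment moves only the nuclear compartment", {
  # halved export rate, noiseless: nuclear fold doubles, cytoplasmic is 1
  base <- rs_steady_state(p_tbl)
  half <- rs_steady_state(update_params(p_tbl, alpha_m = p_tbl$alpha_m / 2))
  expect_equal((half$state[["Nmn"]] / p_tbl$Vn) /
                 (base$state[["Nmn"]] / p_tbl$Vn), 2)
  expect_equal(half$state[["Nmc"]], base$state[["Nmc"]])
  scr <- run_alpha_m_screen(update_params(p_tbl, k0 = p_tbl$k0 / 8),
                            screen_config(n_samples = 400, seed = 2))
  expect_lt(scr$summary$r_kn_cmn, 0)
  expect_lt(abs(scr$summary$r_kn_cmc), 0.05)
})

test_that("volume scans keep concentrations exactly constant under all scaling laws", {
  p3 <- update_params(p_tbl, k0 = p_tbl$k0 / 3)
  vols <- (p_tbl$Vn + p_tbl$Vc) * c(0.5, 1, 2, 4)
  for (law in c("mm", "superlinear", "oscillating")) {
    vs <- volume_scan(p3, volumes = vols, scaling = law)
    expect_true(all(vs$feasible), label = law)
    expect_lt(diff(range(vs$cmc)) / mean(vs$cmc), 1e-9, label = law)
    expect_lt(diff(range(vs$cmn)) / mean(vs$cmn), 1e-9, label = law)
    expect_equal(vs$mrna_fold, vs$volume_fold, tolerance = 1e-9)
    # degradation rate mirrors production per mRNA
    expect_equal(vs$delta_m_fold, vs$kn_fold / vs$mrna_fold,
                 tolerance = 1e-9)
  }
  # MM law: production and degradation folds fall with volume
  vs <- volume_scan(p3, volumes = vols, scaling = "mm")
  expect_true(all(diff(vs$delta_m_fold / vs$kn_fold) < 0))
  # oscillating law: both the production fold and the per-mRNA
  # degradation fold oscillate (non-monotone), and the degradation fold
  # is the production fold per unit mRNA at every volume
  vso <- volume_scan(p3, volumes = seq(20, 80, by = 4),
                     scaling = "oscillating")
  expect_gt(sum(diff(sign(diff(vso$kn_fold))) != 0), 0)
  expect_gt(sum(diff(sign(diff(vso$delta_m_fold))) != 0), 0)
  expect_equal(vso$delta_m_fold, vso$kn_fold / vso$mrna_fold,
               tolerance = 1e-9)
})

test_that("acute depletion produces the three-phase response with consistent flux balance", {
  dep <- acute_depletion_timecourse(p_tbl, fdep = 0.8)
  ph <- dep$phases
  expect_true(all(c(ph$Tacc, ph$Tadp, ph$Trev) > 0))
  expect_lt(ph$plateau_kn_fold, 1)
  expect_gt(ph$peak_mrna_fold, 1)
  # pre-perturbation flatness of the generating steady state
  flat <- rs_simulate(p_tbl, times = seq(0, 50, 5))
  expect_lt(max(abs(flat$Nmc / flat$Nmc[1] - 1)), 1e-7)
  # accumulation phase: production still near baseline while mRNA rises
  tr <- dep$trajectory
  early <- tr$time < 0.5 * ph$Tacc
  expect_true(all(tr$kn_fold[early] > 0.95))
  expect_gt(max(tr$mrna_fold[early]), 1.0)
  # post-perturbation steady state: kn/delta_m = Nmc (flux balance),
  # exact at the relaxed steady state, approached by the trajectory end
  ssp <- dep$steady_post
  expect_equal(ssp$kn / ssp$delta_m, ssp$state[["Nmc"]], tolerance = 1e-9)
  n <- nrow(tr)
  expect_equal(tr$kn[n] / tr$delta_m[n], tr$Nmc[n], tolerance = 1e-2)
  expect_error(acute_depletion_timecourse(p_tbl, fdep = 1.2), "fdep")
})

test_that("depletion phase durations approach their closed-form approximations", {
  dep <- acute_depletion_timecourse(p_tbl, fdep = 0.8)
  ph <- dep$phases
  expect_lt(abs(ph$Tacc - ph$Tacc_approx) / ph$Tacc_approx, 0.30)
  expect_lt(abs(ph$Trev - ph$Trev_approx) / ph$Trev_approx, 0.30)
  # a vanishing perturbation degenerates: peak fold tends to 1
  dep0 <- acute_depletion_timecourse(p_tbl, fdep = 0.01, horizon = 200)
  expect_lt(dep0$phases$peak_mrna_fold, 1.01)
})

test_that("Pol II depletion slows focal-gene decay; the decay rate matches the slow eigenvalue", {
  pd <- polII_depletion_decay(p_tbl, kv_factor = 2)
  expect_true(all(pd$depleted[-1] > pd$control[-1]))
  expect_equal(pd$control[1], 1)
  pd1 <- polII_depletion_decay(p_tbl, kv_factor = 1)
  expect_equal(pd1$control, pd1$depleted)
  # the late-time decay follows the slower of the export and degradation
  # coefficients (two-compartment closed form)
  rates <- attr(pd, "rates")
  slow <- min(rates$export_coef[1], rates$delta_m[1])
  late <- pd$time >= 60
  fit <- one_phase_decay_fit(data.frame(time = pd$time[late],
                                        value = pd$control[late]))
  expect_lt(abs(fit$rate - slow) / slow, 0.10)
  expect_error(polII_depletion_decay(p_tbl, gene_fraction = 0.5), "0.1")
})

test_that("complete transcription shutoff returns X to the nucleus and drains released X", {
  sh <- transcription_shutoff(p_tbl, horizon = 5000, dt = 5)
  n <- nrow(sh)
  expect_gt(sh$NXp[n] / p_tbl$NXt, 0.99)
  expect_lt(max(abs(sh$NXn + sh$NXc + sh$NXp - p_tbl$NXt)) / p_tbl$NXt,
            1e-8)
  # released X decays exponentially at its nuclear-exit rate
  idx <- sh$time <= 60
  fit <- one_phase_decay_fit(data.frame(time = sh$time[idx],
                                        value = sh$NXn[idx]))
  expect_lt(abs(fit$rate - p_tbl$alpha_x) / p_tbl$alpha_x, 0.05)
  # mRNA settles at a lower plateau
  expect_lt(sh$Nmc[n], sh$Nmc[1])
})

test_that("recovery time is measured on the shifted/normalized fold and flags non-recovery", {
  r <- recovery_time(p_tbl, k0_factor = 0.5, horizon = 3000)
  expect_true(r$recovered)
  expect_gt(r$time, 0)
  expect_equal(r$trajectory$fold[1], 1)
  expect_equal(min(r$trajectory$norm_fold), 0)
  # a stricter threshold cannot be reached earlier
  r95 <- recovery_time(p_tbl, k0_factor = 0.5, threshold = 0.95,
                       horizon = 3000)
  expect_gte(r95$time, r$time)
  # too short a horizon flags an infinite recovery, not an error
  r_short <- recovery_time(p_tbl, k0_factor = 0.5, horizon = 100)
  expect_false(r_short$recovered)
  expect_identical(r_short$time, Inf)
  expect_error(recovery_time(p_tbl, k0_factor = 1.5), "k0_factor")
})
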