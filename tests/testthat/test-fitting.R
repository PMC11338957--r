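p_tbl <- rs_params()

test_that("reversion decay fit recovers exact-class parameters to machine precision", {
  tt <- seq(95, 300, by = 1)
  ds <- tibble::tibble(time = tt, total_fold = 1 + 0.3 * exp(-0.018 * tt))
  fit <- fit_reversion_decay(ds)
  expect_equal(fit$a, 0.3, tolerance = 1e-10)
  expect_equal(fit$b, 0.018, tolerance = 1e-10)
  expect_equal(fit$delta_m_rev, fit$b)
  # flat series: decay constant unidentifiable, flagged not errored
  flat <- tibble::tibble(time = tt, total_fold = rep(1, length(tt)))
  ff <- fit_reversion_decay(flat)
  expect_true(ff$degenerate)
  expect_true(is.na(ff$b))
  expect_error(fit_reversion_decay(ds[1:2, ]), "3 points")
})

test_that("the reversion decay constant matches the trajectory's degradation rate", {
  # fit the early reversion window, where the decay-factor pool has
  # settled and the excess mRNA decays as a single exponential; at very
  # long times a small undershoot relaxing on the slow X-redistribution
  # timescale takes over and the one-exponential form no longer applies
  dep <- acute_depletion_timecourse(p_tbl, fdep = 0.8, horizon = 400)
  tr <- dep$trajectory
  seg_start <- dep$phases$T3 + 5
  win <- tr$time <= seg_start + 80
  fit <- fit_reversion_decay(
    tibble::tibble(time = tr$time[win], total_fold = tr$mrna_fold[win]),
    t_start = seg_start)
  delta_m_rev <- dep$steady_post$delta_m
  expect_lt(abs(fit$b - delta_m_rev) / delta_m_rev, 0.10)
})

test_that("one-phase decay fit recovers exact rates and flags constants", {
  tt <- seq(0, 100, by = 2)
  fit <- one_phase_decay_fit(tibble::tibble(time = tt,
                                            value = 5 * exp(-0.05 * tt)))
  expect_equal(fit$rate, 0.05, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-8)
  con <- one_phase_decay_fit(tibble::tibble(time = tt, value = rep(2, 51)))
  expect_true(con$degenerate)
  expect_equal(con$rate, 0)
  expect_error(one_phase_decay_fit(tibble::tibble(time = 1:5,
                                                  value = c(1, -1, 1, 1, 1))))
})

test_that("goodness-of-fit metrics have their documented closed forms", {
  x <- c(1, 2, 3, 4)
  g <- goodness_of_fit(x, x)
  expect_equal(g$mse, 0)
  expect_equal(g$e2, 0)
  expect_equal(g$r2, 1)
  g2 <- goodness_of_fit(x, x + 0.5)
  expect_equal(g2$mse, 0.25)
  expect_equal(g2$e2, 4 * 0.25)
  gc <- goodness_of_fit(c(1, 2), c(3, 3))
  expect_true(is.na(gc$r2))
  expect_error(goodness_of_fit(1:3, 1:4), "length")
  # weights reweight the mean of squared residuals
  gw <- goodness_of_fit(c(0, 0), c(1, 2), weights = c(1, 3))
  expect_equal(gw$mse, (1 * 1 + 3 * 4) / 4)
})

test_that("volume-scaling fit recovers the MM constant and flags the linear regime", {
  syn <- synth_volume_dataset(p_tbl, Kv_true = 5.83,
                              volumes = c(20, 40, 60, 80),
                              noise = noise_spec(FALSE, 0))
  fit <- fit_volume_scaling(syn$dataset, vn_ratio = syn$truth$vn_ratio)
  expect_equal(fit$Kv, 5.83, tolerance = 1e-8)
  expect_false(fit$at_bound)
  # data linear in volume correspond to the infinite-Kv regime
  lin <- tibble::tibble(volume = c(20, 40, 60, 80),
                        kn_fold = c(20, 40, 60, 80) / 40)
  fl <- fit_volume_scaling(lin, v0 = 40)
  expect_true(fl$at_bound)
  expect_error(fit_volume_scaling(tibble::tibble(volume = c(40, 40),
                                                 kn_fold = c(1, 1))),
               "distinct")
})

test_that("staged estimation reproduces the anchor algebra on synthetic data", {
  syn <- synth_depletion_dataset(p_tbl, noise = noise_spec(FALSE, 0, 0))
  st <- staged_initial_estimates(syn$dataset)
  im <- st$intermediates
  # the degradation plateau ratio equals the production plateau ratio
  expect_equal(im$delta_m_rev / im$delta_m_bf, im$r_plateau)
  # assumed anchors propagate through the back-out relations
  expect_equal(st$params$alpha_x, 500 / 5000)
  expect_equal(st$params$alpha_y, 500 / 1000)
  expect_equal(st$params$beta_x, 500 / 2e5)
  expect_equal(st$params$NYt, 1.1e4)
  # phase ordering and TF-pool ordering invariants
  expect_true(im$kn1 >= im$kn2 && im$kn2 >= im$kn3)
  expect_true(im$NXp_bf >= im$NXp2 && im$NXp2 >= im$NXp3)
  # implied cytoplasmic concentration close to the generating ratio
  implied <- rs_steady_state(st$params)
  expect_lt(abs(implied$state[["Nmc"]] / st$params$Vc /
                  (p_tbl$beta_x / p_tbl$beta_m) - 1), 0.15)
  # a stated plateau of 0.4 forces the 0.4 degradation ratio
  ds4 <- syn$dataset
  ds4$nascent_fold[ds4$time >= 95] <- 0.4
  st4 <- staged_initial_estimates(ds4)
  # exactly the plateau ratio by construction; ~0.4 after the robust
  # baseline correction of the nascent series
  expect_equal(st4$intermediates$delta_m_rev / st4$intermediates$delta_m_bf,
               st4$intermediates$r_plateau)
  expect_equal(st4$intermediates$r_plateau, 0.4, tolerance = 2e-3)
  expect_error(staged_initial_estimates(syn$dataset,
                                        assumptions = list(fdep = 0)),
               "fdep")
})

test_that("the optimizer is a descent method with a reproducible objective", {
  syn <- synth_depletion_dataset(p_tbl, times = seq(0, 300, by = 10),
                                 noise = noise_spec(FALSE, 0, 0))
  ds <- syn$dataset
  # optimum at the truth: objective ~ 0 and parameters unchanged
  fit0 <- suppressWarnings(
    optimize_parameters(ds, p_tbl, fdep = 0.8, maxiter = 1))
  expect_lt(fit0$objective, 1e-15)
  expect_equal(unlist(fit0$params[rs_param_names()]),
               unlist(p_tbl[rs_param_names()]), tolerance = 1e-6)
  # from a perturbed start, a few iterations never increase the objective
  start <- p_tbl
  for (nm in c("k0", "Km", "alpha_m", "beta_m", "NXt")) {
    start[[nm]] <- start[[nm]] * 1.2
  }
  start <- validate_params(start)
  fit <- suppressWarnings(
    optimize_parameters(ds, start, fdep = 0.8, maxiter = 4))
  expect_lte(fit$objective, fit$start_objective)
  # objective is recomputable from the returned parameters
  pred <- rsbuffer:::depletion_fold_curves(fit$params, times = ds$time,
                                           fdep = 0.8)
  mse <- mean((c(pred$total_fold, pred$nascent_fold) -
                 c(ds$total_fold, ds$nascent_fold))^2)
  expect_equal(mse, fit$objective, tolerance = 1e-9)
  # broom-style accessors
  td <- tidy(fit)
  expect_identical(td$term, rs_param_names())
  expect_identical(nrow(glance(fit)), 1L)
})
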