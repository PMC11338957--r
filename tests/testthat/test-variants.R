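p_tbl <- rs_params()
core_ss <- rs_steady_state(p_tbl)

test_that("feedback-only null models have the stated closed forms and no buffering", {
  expect_equal(feedback_steady_state("positive", kn = 4, beta_m = 1), 2)
  expect_equal(feedback_steady_state("negative", a = 2, b = 1, beta_m = 1), 1)
  # steady concentration tracks the production parameters: buffering fails
  set.seed(3)
  kns <- runif(200, 1, 100)
  cms <- vapply(kns, function(k) {
    feedback_steady_state("positive", kn = k, beta_m = 0.5)
  }, numeric(1))
  expect_gt(cor(kns, cms), 0.9)
  as <- runif(200, 1, 100)
  cms_n <- vapply(as, function(a) {
    feedback_steady_state("negative", a = a, b = 2, beta_m = 0.5)
  }, numeric(1))
  expect_gt(cor(as, cms_n), 0.9)
  expect_error(feedback_steady_state("positive", kn = -1, beta_m = 1))
})

test_that("variant derivatives satisfy their conservation laws and vanish at the closed-form steady state", {
  for (k in c("nonessential_x", "shuttling_y", "exosome", "dropoff",
              "imprinting")) {
    vp <- rs_variant(k, p_tbl)
    cf <- variant_steady_state(vp)
    d <- variant_derivatives(vp, cf$state)
    expect_lt(max(abs(d)) / max(cf$kn, 1), 1e-9, label = k)
  }
  # conservation for the extended state spaces at a generic state
  vp <- rs_variant("exosome", p_tbl)
  st <- c(core_ss$state, NZn = 500, NZp = 9500)
  d <- variant_derivatives(vp, st)
  expect_lt(abs(d[["NZn"]] + d[["NZp"]]), 1e-9)
  expect_lt(abs(d[["NXn"]] + d[["NXc"]] + d[["NXp"]]), 1e-9)
  vp <- rs_variant("pabpc1", p_tbl)
  st <- c(core_ss$state, NPn = 1000, NPc = 2000)
  d <- variant_derivatives(vp, st)
  # total P = free P plus the mRNA-bound pools (tight binding)
  expect_lt(abs(d[["NPn"]] + d[["NPc"]] + d[["Nmn"]] + d[["Nmc"]]), 1e-9)
  expect_error(variant_derivatives(vp, core_ss$state), "pabpc1")
})

test_that("closed-form steady states agree with long-horizon relaxation", {
  for (k in c("nonessential_x", "shuttling_y", "exosome", "dropoff",
              "imprinting")) {
    vp <- rs_variant(k, p_tbl)
    cf <- variant_steady_state(vp)
    expect_false(cf$numeric_only)
    relaxed <- variant_relax(vp)
    rel_err <- max(abs(relaxed - cf$state[names(relaxed)]) /
                     pmax(abs(cf$state[names(relaxed)]), 1))
    expect_lt(rel_err, 1e-6, label = k)
  }
})

test_that("variants reduce to the core model in their limits", {
  # drop-off with no premature termination is the core model (compared at
  # an out-of-equilibrium state so the derivatives are O(1))
  vp0 <- rs_variant("dropoff", p_tbl, delta = 1e-15)
  s_off <- core_ss$state
  s_off[["Nmc"]] <- 2 * s_off[["Nmc"]]
  d_var <- variant_derivatives(vp0, s_off)
  d_core <- rs_derivatives(s_off, p_tbl)
  expect_equal(unclass(d_var), unclass(d_core), tolerance = 1e-9)
  cf0 <- variant_steady_state(vp0)
  expect_equal(cf0$cmc, p_tbl$beta_x / p_tbl$beta_m, tolerance = 1e-9)
  # non-essential X with no X-independent production restores buffering
  cf <- variant_steady_state(rs_variant("nonessential_x", p_tbl, k1 = 1e-12))
  expect_equal(cf$cmc, p_tbl$beta_x / p_tbl$beta_m, tolerance = 1e-9)
  # exosome with no nuclear degradation restores the core nuclear pool
  cf <- variant_steady_state(rs_variant("exosome", p_tbl, alpha_d = 1e-18))
  expect_equal(cf$state[["Nmn"]],
               p_tbl$alpha_y / p_tbl$alpha_m * p_tbl$Vn, tolerance = 1e-9)
  # imprinting and shuttling-Y leave both steady concentrations unchanged
  for (k in c("imprinting", "shuttling_y")) {
    cf <- variant_steady_state(rs_variant(k, p_tbl))
    expect_equal(cf$cmn, p_tbl$alpha_y / p_tbl$alpha_m, label = k)
    expect_equal(cf$cmc, p_tbl$beta_x / p_tbl$beta_m, label = k)
  }
})

test_that("drop-off scales both mRNA concentrations by exactly 1 - delta", {
  for (d in c(0.2, 0.5)) {
    cf <- variant_steady_state(rs_variant("dropoff", p_tbl, delta = d))
    expect_equal(cf$cmn, (1 - d) * p_tbl$alpha_y / p_tbl$alpha_m)
    expect_equal(cf$cmc, (1 - d) * p_tbl$beta_x / p_tbl$beta_m)
  }
  expect_error(rs_variant("dropoff", p_tbl, delta = 1.2), "delta")
})

test_that("non-essential X breaks buffering: the cytoplasmic concentration varies with the TF pool and volume", {
  set.seed(11)
  cmcs <- replicate(100, {
    q <- update_params(p_tbl,
                       NXt = p_tbl$NXt * rlnorm(1, 0, 0.4),
                       Vn = p_tbl$Vn * rlnorm(1, 0, 0.4))
    variant_steady_state(rs_variant("nonessential_x", q))$cmc
  })
  expect_gt(sd(cmcs) / mean(cmcs), 0.01)
})

test_that("host-shutoff degradation step drives the five directional responses", {
  vi <- viral_infection_timecourse(beta_m_factor = 10, horizon = 3000)
  n <- nrow(vi)
  expect_gt(vi$delta_m_fold[n], 1)
  expect_lt(vi$kn_fold[n], 1)
  expect_lt(vi$mrna_fold[n], 1)
  expect_gt(vi$nuclear_P_fold[n], 1)
  expect_lt(vi$cytoplasmic_P_fold[n], 1)
  # terminal cytoplasmic concentration from the scaled flux balance
  p20 <- update_params(p_tbl, alpha_m = 20 * p_tbl$alpha_m)
  expect_equal(vi$Nmc[n] / p20$Vc, p20$beta_x / (10 * p20$beta_m),
               tolerance = 1e-6)
  expect_error(viral_infection_timecourse(beta_m_factor = 0), "positive")
})

test_that("independent gene groups do not couple: the unperturbed group is exactly constant", {
  tg <- two_group_timecourse(xc_factor = 0.1, horizon = 300, dt = 2)
  expect_lt(max(abs(tg$mrna_fold_2 - 1)), 1e-8)
  expect_gt(max(tg$mrna_fold_1), 1.05)
  # the combined fold is the copy-number-weighted mean of the group folds
  s1 <- rs_steady_state(p_tbl)$state
  m1 <- s1[["Nmn"]] + s1[["Nmc"]]
  expect_equal(tg$total_fold,
               (tg$mrna_fold_1 * m1 + tg$mrna_fold_2 * m1) / (2 * m1))
})

test_that("variant construction validates kinds and extras", {
  expect_error(rs_variant("unknown_kind"), "unknown variant")
  expect_error(rs_variant("exosome", p_tbl, alpha_d = -1), "positive")
  expect_error(rs_variant("shuttling_y", p_tbl, delta = 0.1), "unknown extra")
  vp <- rs_variant("ShUtTlInG_y", p_tbl)  # case-insensitive
  expect_identical(vp$kind, "shuttling_y")
})
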