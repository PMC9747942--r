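test_that("fit_distribution moment-matches beta and lognormal, bounds uniform", {
  # beta example: moment-matching algebra with SD = range/3.92
  sp <- fit_distribution("beta", 0.0646, 0.0485, 0.0808)
  s <- (0.0808 - 0.0485) / 3.92
  alpha <- 0.0646 * (0.0646 * (1 - 0.0646) / s^2 - 1)
  expect_equal(sp$alpha, alpha, tolerance = 1e-12)
  expect_equal(sp$alpha, 57.4, tolerance = 0.01)
  expect_equal(sp$beta, alpha * (1 - 0.0646) / 0.0646, tolerance = 1e-12)
  expect_equal(sp$beta, 831.4, tolerance = 0.01)
  # fitted beta mean equals the target mean analytically
  expect_equal(sp$alpha / (sp$alpha + sp$beta), 0.0646, tolerance = 1e-12)
  # uniform: the range is used directly as hard bounds
  su <- fit_distribution("uniform", 0.42, 0.315, 0.525)
  set.seed(1)
  x <- sample_distribution(su, 1e5)
  expect_true(all(x >= 0.315 & x <= 0.525))
  expect_equal(mean(x), 0.42, tolerance = 0.005)
  # lognormal: mean recovered by the law of large numbers
  sl <- fit_distribution("lognormal", 13.36, 11.62, 15.82)
  set.seed(2)
  y <- sample_distribution(sl, 1e6)
  expect_equal(mean(y), 13.36, tolerance = 0.01)
  expect_true(all(y > 0))
  # error paths
  expect_error(fit_distribution("beta", 0.5, 0, 4), "infeasible")
  expect_error(fit_distribution("beta", 1.2, 0.1, 0.2), "mean in")
  expect_error(fit_distribution("lognormal", -1, 0.5, 2), "mean > 0")
  expect_identical(sample_distribution(fit_distribution("fixed", 7, 7, 7), 3),
                   rep(7, 3))
})

test_that("every sampled parameter respects its support and recovers its mean", {
  specs <- psa_distributions(base_params)
  expect_gt(length(specs), 40)
  set.seed(5)
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    x <- sample_distribution(sp, 1e5)
    if (sp$family == "beta") expect_true(all(x >= 0 & x <= 1), info = nm)
    if (sp$family == "lognormal") expect_true(all(x > 0), info = nm)
    if (sp$family == "uniform") {
      expect_true(all(x >= sp$low & x <= sp$high), info = nm)
    }
    # moment matching is mean-unbiased for beta and lognormal tags
    if (sp$family %in% c("beta", "lognormal")) {
      expect_equal(mean(x), param_value(base_params, nm),
                   tolerance = 0.01, info = nm)
    }
  }
})

test_that("degenerate distributions reproduce the base case exactly", {
  p <- base_params
  for (nm in names(p$fields)) {   # collapse every range onto the base
    p$fields[[nm]]$low <- p$fields[[nm]]$base
    p$fields[[nm]]$high <- p$fields[[nm]]$base
    p$fields[[nm]]$dist <- "fixed"
  }
  cfg <- sim_config(n = 1500, seed = 23)
  ps <- psa(p, n_iter = 2, config = cfg, seed = 23)
  for (i in 1:2) {
    it_cfg <- cfg
    it_cfg$seed <- prediabsim:::stream_seed(23, i, 800L)
    direct <- prediabsim:::run_pair(p, it_cfg, "S1")
    expect_identical(
      ps$outcomes$cost[ps$outcomes$iter == i & ps$outcomes$strategy == "S1"],
      direct$S1$per_capita_cost)
  }
  expect_equal(ps$n_rejected, 0)
})

test_that("psa is deterministic and summarizes cost-effectiveness", {
  cfg <- sim_config(n = 1000, seed = 29)
  a <- psa(base_params, n_iter = 3, config = cfg, seed = 29)
  b <- psa(base_params, n_iter = 3, config = cfg, seed = 29)
  expect_identical(a$draws, b$draws)
  expect_identical(a$icers$icer, b$icers$icer)
  expect_equal(nrow(a$icers), 9)  # 3 comparisons x 3 iterations
  pce <- a$summary$p_cost_effective
  expect_true(all(pce$cost_effective >= 0 & pce$cost_effective <= 1))
  cc <- ceac(a, wtp_grid = c(0, 12551, 1e6))
  expect_equal(nrow(cc), 9)
  # acceptability is monotone non-decreasing in WTP for each comparison
  for (cmpr in unique(cc$comparator)) {
    sub <- cc[cc$comparator == cmpr, ]
    expect_true(all(diff(sub$p_cost_effective[order(sub$wtp)]) >= 0))
  }
})

test_that("one_way spreads vanish when the range is degenerate or inert", {
  cfg <- sim_config(n = 1200, seed = 37)
  p <- base_params
  p$fields$fpg_cost$low <- p$fields$fpg_cost$base
  p$fields$fpg_cost$high <- p$fields$fpg_cost$base
  e <- one_way("fpg_cost", p, cfg)
  expect_identical(e$spread, 0)   # identical params => identical paired runs
  # a prevalence band nobody occupies cannot move the ICER: all baseline
  # ages below 40, so the >60 prevalence band is never read
  young <- demography_model(mean_age = 30, age_sd = 6, age_min = 18,
                            age_max = 40)
  cfg_y <- sim_config(n = 1200, seed = 37, demography = young)
  e2 <- one_way("prev_t2dm_gt60", base_params, cfg_y)
  expect_identical(e2$spread, 0)
  expect_error(one_way("nope", base_params, cfg), "unknown")
})

test_that("tornado ranks fields by spread", {
  cfg <- sim_config(n = 1500, seed = 41)
  tn <- tornado(base_params, cfg,
                fields = c("discount_rate", "ogtt_cost", "cdrs_fp_ngt"))
  expect_equal(nrow(tn), 3)
  expect_true(all(diff(tn$spread) <= 0))
  expect_equal(tn$rank, 1:3)
  expect_true(all(is.finite(tn$icer_low) & is.finite(tn$icer_high)))
})

test_that("compliance_scan returns the published table's shape", {
  cfg <- sim_config(n = 1500, seed = 43)
  cs <- compliance_scan(c(1, 0.5), base_params, cfg)
  expect_equal(nrow(cs), 6)  # 2 rates x 3 strategies
  expect_true(all(is.na(cs$icer_vs_control[cs$strategy == "CONTROL"])))
  expect_true(all(is.finite(cs$icer_vs_control[cs$strategy != "CONTROL"])))
})
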