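test_that("first-line operating characteristics map states to published values", {
  p <- base_params
  cases <- list(
    list("T2DM", "CDRS", 0.876),
    list("NGT", "CDRS", 0.4474),
    list("iIFG", "CDRS", 0.7339),
    list("iIGT", "CDRS", 0.7339),
    list("IFG_IGT", "CDRS", 0.7339),  # one common pre-DM sensitivity
    list("T2DM", "FPG", 0.7342),
    list("iIFG", "FPG", 0.4609),
    list("IFG_IGT", "FPG", 0.6974),
    list("iIGT", "FPG", 0.0),         # FPG blind to isolated IGT (default)
    list("NGT", "FPG", 0.10)
  )
  for (cs in cases) {
    expect_equal(first_line_positive_prob(cs[[1]], cs[[2]], p), cs[[3]],
                 info = paste(cs[[1]], cs[[2]]))
  }
})

test_that("offered_test implements the three cascades and D9 compliance", {
  p <- base_params
  goer <- make_individual(exam_goer = TRUE)
  nongoer <- make_individual(exam_goer = FALSE)
  expect_equal(offered_test(goer, "CONTROL", p), "FPG")
  expect_equal(offered_test(nongoer, "CONTROL", p), "NONE")
  expect_equal(offered_test(goer, "S1", p), "CDRS")
  expect_equal(offered_test(goer, "S2", p), "FPG")
  # compliance gates only self-administered CDRS among non-exam-goers
  p0 <- perturb(p, "compliance", 0)
  p1 <- perturb(p, "compliance", 1)
  expect_equal(offered_test(nongoer, "S1", p0), "NONE")
  expect_equal(offered_test(nongoer, "S1", p1), "CDRS")
  expect_equal(offered_test(nongoer, "S2", p1), "CDRS")
  expect_equal(offered_test(goer, "S1", p0), "CDRS")   # exam CDRS unaffected
  diag <- make_individual(diagnosed = TRUE)
  expect_error(offered_test(diag, "S1", p), "undiagnosed")
})

test_that("expected per-screen cost matches the enumeration oracle", {
  p <- base_params
  # oracle: enumerate the test-result uniform on a fine grid
  grid <- seq(0.5 / 4000, 1 - 0.5 / 4000, length.out = 4000)
  for (test in c("FPG", "CDRS")) {
    for (state in c("NGT", "iIFG", "iIGT", "IFG_IGT", "T2DM")) {
      ind <- make_individual(state = state, exam_goer = TRUE)
      strat <- if (test == "FPG") "CONTROL" else "S1"
      costs <- vapply(grid, function(u) {
        screen_once(ind, strat, p, rng = c(0, u))$cost
      }, 0.0)
      p_pos <- first_line_positive_prob(state, test, p)
      first_unit <- if (test == "FPG") 5.49 else 0
      expect_equal(mean(costs), first_unit + p_pos * 13.36,
                   tolerance = 0.01, info = paste(state, test))
    }
  }
})

test_that("screen_once diagnoses via OGTT as gold standard", {
  p <- base_params
  # positive first-line draw (u2 = 0 < any positive sensitivity)
  out <- screen_once(make_individual("iIFG"), "CONTROL", p, rng = c(0, 0))
  expect_true(out$ogtt_done)
  expect_equal(out$new_diagnosis, "preDM")
  expect_equal(out$cost, 5.49 + 13.36)
  out_t2 <- screen_once(make_individual("T2DM"), "S1", p, rng = c(0, 0))
  expect_equal(out_t2$new_diagnosis, "T2DM")
  expect_equal(out_t2$cost, 13.36)  # CDRS free, OGTT charged
  # false-positive NGT: OGTT cost but no diagnosis
  out_fp <- screen_once(make_individual("NGT"), "S1", p, rng = c(0, 0.2))
  expect_true(out_fp$ogtt_done)
  expect_equal(out_fp$new_diagnosis, "none")
  expect_equal(out_fp$cost, 13.36)
  # negative first-line: no OGTT, first-line cost only
  out_neg <- screen_once(make_individual("NGT"), "S1", p, rng = c(0, 0.99))
  expect_false(out_neg$ogtt_done)
  expect_equal(out_neg$cost, 0)
  # no test offered
  out_none <- screen_once(make_individual("NGT", exam_goer = FALSE),
                          "CONTROL", p)
  expect_equal(out_none$first_line_test, "NONE")
  expect_equal(out_none$cost, 0)
})

test_that("NGT false-positive probability drives the OGTT cost distribution", {
  p <- base_params
  ind <- make_individual("NGT", exam_goer = TRUE)
  u <- seq(0.5 / 1e4, 1 - 0.5 / 1e4, length.out = 1e4)
  costs <- vapply(u, function(x) screen_once(ind, "S1", p, rng = c(0, x))$cost, 0.0)
  expect_equal(mean(costs == 13.36), 0.4474, tolerance = 0.001)
  expect_equal(mean(costs == 0), 1 - 0.4474, tolerance = 0.001)
})

test_that("sunk-cost accounting zeroes exam-embedded FPG only", {
  p <- base_params
  opt <- sim_options(treat_exam_fpg_as_sunk = TRUE)
  out <- screen_once(make_individual("NGT"), "CONTROL", p, rng = c(0, 0.99),
                     options = opt)
  expect_equal(out$cost, 0)
  out2 <- screen_once(make_individual("NGT"), "CONTROL", p, rng = c(0, 0.99))
  expect_equal(out2$cost, 5.49)
})

test_that("zero sensitivities imply no OGTT and no diagnoses anywhere", {
  res <- run_cohort(2000, "S1", zero_sensitivity_params,
                    life_table = base_life_table, seed = 4)
  expect_equal(res$per_capita_cost, 0)  # CDRS free and no OGTT ever
  res2 <- run_cohort(2000, "S2", zero_sensitivity_params,
                     life_table = base_life_table, seed = 4)
  # only first-line FPG unit costs can accrue, never an OGTT or diagnosis
  co <- build_cohort(2000, zero_sensitivity_params, base_demography, seed = 4)
  expect_lte(res2$per_capita_cost,
             mean(co$exam_goer) * 5.49 * res2$cycles)
})

test_that("annual intervention cost is sessions/year times unit cost", {
  expect_equal(annual_intervention_cost(base_params), 53.32)
  expect_equal(annual_intervention_cost(
    perturb(base_params, "interventions_per_year", 1)), 26.66)
  expect_equal(annual_intervention_cost(
    perturb(base_params, "intervention_cost", 0)), 0)
})
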