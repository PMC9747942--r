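test_that("transition_distribution reproduces the published structure", {
  p <- base_params
  d <- transition_distribution("iIGT", FALSE, 65, p)
  expect_equal(unname(d["T2DM"]), 0.0791)
  expect_equal(unname(d["NGT"]), 0.0883)
  expect_equal(unname(d["iIGT"]), 1 - 0.0791 - 0.0883)
  expect_equal(unname(transition_distribution("IFG_IGT", TRUE, 45, p)["T2DM"]),
               0.0556)
  expect_equal(unname(transition_distribution("T2DM", TRUE, 50, p)["T2DM"]), 1)
  # NGT never progresses directly to T2DM
  ngt <- transition_distribution("NGT", FALSE, 44, p)
  expect_equal(unname(ngt["T2DM"]), 0)
  expect_equal(unname(ngt["iIGT"]), 0.0646)
  # diagnosis slows i-IGT progression but (per the source data) raises i-IFG
  expect_lt(unname(transition_distribution("iIGT", TRUE, 65, p)["T2DM"]),
            unname(transition_distribution("iIGT", FALSE, 65, p)["T2DM"]))
  # every row sums to one across the age/diagnosis grid
  for (st in c("NGT", "iIFG", "iIGT", "IFG_IGT", "T2DM")) {
    for (dg in c(FALSE, TRUE)) {
      for (a in c(18, 39, 40, 49, 50, 59, 60, 79)) {
        expect_equal(sum(transition_distribution(st, dg, a, p)), 1,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("a diagnosed pre-DM year costs exactly the intervention outlay at r=0", {
  p0 <- perturb(base_params, "discount_rate", 0)
  ind <- make_individual("iIFG", age = 45, diagnosed = TRUE)
  out <- step_individual(ind, "CONTROL", p0, deathless_life_table,
                         cycle_index = 0)
  expect_equal(out$cost, 53.32)
  expect_equal(out$age, 46L)
  # with discounting, a cycle-1 outlay is divided by 1.05 exactly
  out2 <- step_individual(ind, "CONTROL", base_params, deathless_life_table,
                          cycle_index = 1)
  expect_equal(out2$cost, 53.32 / 1.05)
  dead <- make_individual()
  dead$alive <- FALSE
  dead$state <- "DEAD"
  expect_error(step_individual(dead, "CONTROL", p0, deathless_life_table, 0),
               "dead")
})

test_that("trajectories are deterministic and states are conserved", {
  r1 <- run_cohort(3000, "S2", base_params, life_table = base_life_table,
                   seed = 21)
  r2 <- run_cohort(3000, "S2", base_params, life_table = base_life_table,
                   seed = 21)
  expect_identical(r1$per_capita_cost, r2$per_capita_cost)
  expect_identical(r1$cum_t2dm_prev, r2$cum_t2dm_prev)
  expect_identical(r1$final_state_dist, r2$final_state_dist)
  expect_equal(sum(r1$final_state_dist), 1, tolerance = 1e-12)
  # step-by-step conservation and flag invariants on a small cohort
  co <- build_cohort(500, base_params, base_demography, seed = 8)
  co$t2dm_weight <- as.numeric(co$ever_t2dm)
  lm <- prediabsim:::life_table_matrix(base_life_table)
  for (cyc in 0:9) {
    co <- prediabsim:::step_cohort(co, "S1", base_params, lm, cyc, 8,
                                   sim_options(), 80)
    expect_equal(nrow(co), 500)
    expect_identical(co$state == "DEAD", !co$alive)
    expect_true(all(co$ever_t2dm[co$state == "T2DM"]))
    expect_false(any(co$diagnosed[co$state == "NGT"]))
    expect_true(all(co$cost >= 0))
  }
})

test_that("disabled screening makes strategies indistinguishable", {
  p <- perturb(perturb(base_params, "exam_rate", 0), "compliance", 0)
  a <- run_cohort(5000, "CONTROL", p, life_table = base_life_table, seed = 13)
  b <- run_cohort(5000, "S1", p, life_table = base_life_table, seed = 13)
  expect_identical(a$cum_t2dm_prev, b$cum_t2dm_prev)
  expect_identical(a$per_capita_cost, b$per_capita_cost)
  expect_equal(a$per_capita_cost, 0)  # nobody is ever tested
})

test_that("no progression and no initial disease give zero prevalence", {
  p <- base_params
  for (f in grep("^trans_.*_t2dm_", names(p$fields), value = TRUE)) {
    p <- perturb(p, f, 0)
  }
  for (f in grep("^prev_t2dm_", names(p$fields), value = TRUE)) {
    p <- perturb(p, f, 0)
  }
  r <- run_cohort(3000, "CONTROL", p, life_table = base_life_table, seed = 2)
  expect_equal(r$cum_t2dm_prev, 0)
})

test_that("microsimulation agrees with the expectation oracle (spot check)", {
  or <- expected_occupancy("S2", base_params, base_life_table,
                           base_demography)
  mc <- run_cohort(15000, "S2", base_params, life_table = base_life_table,
                   seed = 31)
  se <- sqrt(or$cum_t2dm_prev * (1 - or$cum_t2dm_prev) / 15000)
  expect_lt(abs(mc$cum_t2dm_prev - or$cum_t2dm_prev), 4 * se)
  expect_equal(mc$per_capita_cost, or$per_capita_cost, tolerance = 0.05)
})

test_that("common random numbers pair cohorts across strategies", {
  a <- run_cohort(2000, "CONTROL", base_params, life_table = base_life_table,
                  seed = 17)
  b <- run_cohort(2000, "S1", base_params, life_table = base_life_table,
                  seed = 17)
  ca <- build_cohort(2000, base_params, base_demography, seed = 17)
  cb <- build_cohort(2000, base_params, base_demography, seed = 17)
  expect_identical(ca, cb)  # same people enter both arms
  expect_false(identical(a$per_capita_cost, b$per_capita_cost))
})

test_that("CI machinery brackets the point estimate", {
  r <- run_cohort(5000, "CONTROL", base_params, life_table = base_life_table,
                  seed = 19)
  expect_lte(r$ci_cost[1], r$per_capita_cost)
  expect_gte(r$ci_cost[2], r$per_capita_cost)
  expect_lte(r$ci_prev[1], r$cum_t2dm_prev)
  expect_gte(r$ci_prev[2], r$cum_t2dm_prev)
  expect_length(r$batch_cost, 50)
})
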