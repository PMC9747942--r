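# Shared fixtures, built in code. Loaded once per test run.

base_params <- default_params()
base_demography <- demography_model()
base_life_table <- synth_life_table(base_demography)

# life table with no mortality before the closing age (for cost arithmetic)
deathless_life_table <- local({
  lt <- base_life_table
  lt$qx <- 0
  lt$qx[lt$age == 100] <- 1
  lt
})

# life table where everyone dies in the first cycle
lethal_life_table <- local({
  lt <- base_life_table
  lt$qx <- 1
  lt
})

# a one-person cohort in a chosen condition
make_individual <- function(state = "NGT", age = 45, diagnosed = FALSE,
                            exam_goer = TRUE, params = base_params,
                            seed = 42) {
  ind <- build_cohort(1, params, base_demography, seed = seed)
  ind$state <- state
  ind$age <- as.integer(age)
  ind$diagnosed <- diagnosed
  ind$exam_goer <- exam_goer
  ind$ever_t2dm <- state == "T2DM"
  ind
}

# fabricate a cohort_result with known means (for ICER arithmetic tests)
fake_result <- function(strategy, cost, prev, n = 1000L, seed = 1L,
                        n_batches = 50L, jitter = 0) {
  set.seed(7)
  bc <- cost + jitter * stats::rnorm(n_batches)
  bp <- prev + jitter * stats::rnorm(n_batches) / 100
  structure(list(strategy = strategy, n = n, seed = seed, horizon_age = 80,
                 per_capita_cost = mean(bc), cum_t2dm_prev = mean(bp),
                 ci_cost = range(bc), ci_prev = range(bp),
                 batch_cost = bc, batch_prev = bp,
                 final_state_dist = rep(1 / 6, 6),
                 state_levels = c("NGT", "iIFG", "iIGT", "IFG_IGT",
                                  "T2DM", "DEAD"),
                 cycles = 62L),
            class = "cohort_result")
}

# set all first-line operating characteristics to zero
zero_sensitivity_params <- local({
  p <- base_params
  for (f in c("fpg_sens_t2dm", "fpg_sens_iifg", "fpg_sens_iigt",
              "fpg_sens_ifgigt", "fpg_fp_ngt", "cdrs_sens_t2dm",
              "cdrs_sens_prediab", "cdrs_fp_ngt")) {
    p <- perturb(p, f, 0)
  }
  p
})
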