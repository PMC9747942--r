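# Annual-cycle microsimulation. Within each cycle the event order is:
# (1) screening, (2) lifestyle-intervention accounting for diagnosed
# pre-diabetes, (3) glycemic transition (diagnosis-dependent progression),
# (4) mortality, (5) ageing -- so a diagnosis made in year k already slows
# (or, for i-IFG, alters) the year-k transition. Costs accrued in cycle t are
# discounted by (1+r)^(-t). Simulation stops at death or the 80th birthday.
#
# Strategies run with the same seed share the cohort and every decision
# uniform (common random numbers), so strategy contrasts are paired.

CH_OFFER <- 11L
CH_FIRST <- 12L
CH_TRANS <- 13L
CH_DEATH <- 14L

#' Annual transition distribution for one individual profile
#'
#' NGT can move to any pre-diabetes substate but never directly to T2DM;
#' pre-diabetes can progress to T2DM (probability depending on substate,
#' diagnosis status -- diagnosed patients are under lifestyle intervention --
#' and age band) or revert to NGT; T2DM is absorbing among living states.
#'
#' @param state "NGT", "iIFG", "iIGT", "IFG_IGT" or "T2DM".
#' @param diagnosed Logical.
#' @param age Age in years, >= 18.
#' @param params A `param_set`.
#' @return Named probability vector over destinations
#'   (NGT, iIFG, iIGT, IFG_IGT, T2DM), summing to 1.
#' @export
transition_distribution <- function(state, diagnosed, age, params) {
  stopifnot(length(state) == 1L, state %in% setdiff(STATE_LEVELS, "DEAD"))
  v <- function(nm) param_value(params, nm)
  out <- c(NGT = 0, iIFG = 0, iIGT = 0, IFG_IGT = 0, T2DM = 0)
  if (state == "NGT") {
    out["iIFG"] <- v("trans_ngt_iifg")
    out["iIGT"] <- v("trans_ngt_iigt")
    out["IFG_IGT"] <- v("trans_ngt_ifgigt")
    out["NGT"] <- 1 - sum(out)
  } else if (state == "T2DM") {
    out["T2DM"] <- 1
  } else {
    key <- c(iIFG = "iifg", iIGT = "iigt", IFG_IGT = "ifgigt")[[state]]
    p_t2dm <- band_lookup(progression_table(params, key, diagnosed), age)
    p_rev <- v(paste0("trans_", key, "_ngt"))
    out["T2DM"] <- p_t2dm
    out["NGT"] <- p_rev
    out[state] <- 1 - p_t2dm - p_rev
    if (out[state] < 0) stopf("transition probabilities for %s sum to > 1", state)
  }
  out
}

# Vectorized one-cycle update. `active` marks alive individuals under the
# horizon; everyone else is untouched. Uniform vectors are full-length so
# individual i consumes the same draw under every strategy.
step_cohort <- function(cohort, strategy, params, life_mat, cycle, seed,
                        options, horizon_age) {
  n <- nrow(cohort)
  active <- cohort$alive & cohort$age < horizon_age
  if (!any(active)) return(cohort)
  r <- param_value(params, "discount_rate")
  disc <- (1 + r)^(-cycle)

  # (1) screening
  u_offer <- channel_runif(n, seed, cycle, CH_OFFER)
  u_first <- channel_runif(n, seed, cycle, CH_FIRST)
  sub <- cohort
  sub$alive <- active
  sc <- screen_cycle(sub, strategy, params, u_offer, u_first, options)
  newly <- sc$new_diagnosis != "none"
  cohort$diagnosed[newly] <- TRUE
  cycle_cost <- sc$cost

  # (2) lifestyle intervention while diagnosed pre-diabetic
  interv <- active & cohort$diagnosed & cohort$state %in% PREDM_STATES &
    cohort$years_intervened < options$intervention_years_cap
  cycle_cost[interv] <- cycle_cost[interv] + annual_intervention_cost(params)
  on_interv <- active & cohort$diagnosed & cohort$state %in% PREDM_STATES
  cohort$years_intervened[on_interv] <- cohort$years_intervened[on_interv] + 1L

  cohort$cost <- cohort$cost + cycle_cost * disc

  # (3) glycemic transition -- all moves computed from the pre-transition
  # state snapshot so nobody transitions twice in one cycle
  u_trans <- channel_runif(n, seed, cycle, CH_TRANS)
  v <- function(nm) param_value(params, nm)
  state0 <- cohort$state
  diagnosed0 <- cohort$diagnosed
  idx_ngt <- which(active & state0 == "NGT")
  if (length(idx_ngt)) {
    u <- u_trans[idx_ngt]
    c1 <- v("trans_ngt_iifg")
    c2 <- c1 + v("trans_ngt_iigt")
    c3 <- c2 + v("trans_ngt_ifgigt")
    st <- rep("NGT", length(idx_ngt))
    st[u < c3] <- "IFG_IGT"
    st[u < c2] <- "iIGT"
    st[u < c1] <- "iIFG"
    cohort$state[idx_ngt] <- st
  }
  for (sub_state in PREDM_STATES) {
    key <- c(iIFG = "iifg", iIGT = "iigt", IFG_IGT = "ifgigt")[[sub_state]]
    idx <- which(active & state0 == sub_state)
    if (!length(idx)) next
    p_rev <- v(paste0("trans_", key, "_ngt"))
    for (dg in c(FALSE, TRUE)) {
      ii <- idx[diagnosed0[idx] == dg]
      if (!length(ii)) next
      p_t2dm <- band_lookup(progression_table(params, key, dg), cohort$age[ii])
      u <- u_trans[ii]
      to_t2dm <- u < p_t2dm
      to_ngt <- !to_t2dm & u < p_t2dm + p_rev
      if (any(to_t2dm)) {
        j <- ii[to_t2dm]
        cohort$state[j] <- "T2DM"
        newt <- j[!cohort$ever_t2dm[j]]
        cohort$ever_t2dm[newt] <- TRUE
        if (options$discount_effects) {
          cohort$t2dm_weight[newt] <- (1 + r)^(-cycle)
        }
      }
      if (any(to_ngt)) {
        j <- ii[to_ngt]
        cohort$state[j] <- "NGT"
        cohort$diagnosed[j] <- FALSE  # health status changed; back in the pool
        cohort$years_intervened[j] <- 0L
      }
    }
  }

  # (4) mortality at the attained age
  u_death <- channel_runif(n, seed, cycle, CH_DEATH)
  ia <- which(active)
  qx <- life_mat[cbind(pmin(cohort$age[ia], 100) + 1L,
                       match(cohort$sex[ia], c("M", "F")))]
  dies <- ia[u_death[ia] < qx]
  if (length(dies)) {
    cohort$alive[dies] <- FALSE
    cohort$state[dies] <- "DEAD"
  }

  # (5) ageing
  survivors <- active & cohort$alive
  cohort$age[survivors] <- cohort$age[survivors] + 1L
  cohort
}

#' Advance one individual by one annual cycle
#'
#' Single-person wrapper around the cohort step, mainly for inspection and
#' tests; the engine itself is vectorized.
#'
#' @param individual One-row `cohort`.
#' @param strategy "CONTROL", "S1" or "S2".
#' @param params A `param_set`.
#' @param life_table A `life_table`.
#' @param cycle_index Cycle number (0-based; costs discounted by
#'   `(1+r)^-cycle_index`).
#' @param seed Integer seed driving this individual's draws.
#' @param options A [sim_options()].
#' @param horizon_age Simulation stops at this birthday.
#' @return The updated one-row `cohort`.
#' @export
step_individual <- function(individual, strategy, params, life_table,
                            cycle_index, seed = 1L, options = sim_options(),
                            horizon_age = 80) {
  stopifnot(nrow(individual) == 1L)
  if (!individual$alive) stopf("step_individual: individual is dead")
  if (is.null(individual$t2dm_weight)) {
    individual$t2dm_weight <- as.numeric(individual$ever_t2dm)
  }
  step_cohort(individual, strategy, params, life_table_matrix(life_table),
              cycle_index, seed, options, horizon_age)
}

#' Simulate a cohort under one screening strategy
#'
#' Builds the cohort (identically for every strategy sharing `seed`), runs
#' annual cycles until everyone is dead or has reached `horizon_age`, and
#' aggregates to the per-capita discounted lifetime cost and the cumulative
#' T2DM prevalence (ever entered T2DM by the horizon, dead included, over
#' all n simulated people -- individuals already in undiagnosed T2DM at
#' baseline count from cycle 0). 95% CIs come from a normal approximation
#' over `n_batches` equal batch means.
#'
#' @param n Cohort size, >= 1.
#' @param strategy "CONTROL", "S1" or "S2".
#' @param params A `param_set`.
#' @param life_table A `life_table` (default: synthetic).
#' @param demography A [demography_model()].
#' @param seed Integer seed; reuse across strategies for paired comparisons.
#' @param horizon_age Terminal age (default 80).
#' @param n_batches Batches for CI construction (default 50).
#' @param options A [sim_options()].
#' @return A `cohort_result`.
#' @export
run_cohort <- function(n, strategy, params, life_table = NULL,
                       demography = demography_model(), seed = 1L,
                       horizon_age = 80, n_batches = 50,
                       options = sim_options()) {
  stopifnot(strategy %in% STRATEGY_LEVELS)
  if (is.null(life_table)) life_table <- synth_life_table(demography)
  cohort <- build_cohort(n, params, demography, seed)
  cohort$t2dm_weight <- as.numeric(cohort$ever_t2dm)
  life_mat <- life_table_matrix(life_table)
  cycle <- 0L
  while (any(cohort$alive & cohort$age < horizon_age)) {
    cohort <- step_cohort(cohort, strategy, params, life_mat, cycle, seed,
                          options, horizon_age)
    cycle <- cycle + 1L
    if (cycle > 200L) stopf("run_cohort: cycle limit exceeded")  # safety
  }
  eff <- if (options$discount_effects) cohort$t2dm_weight else
    as.numeric(cohort$ever_t2dm)
  batch <- ((cohort$id - 1L) %% n_batches) + 1L
  batch_cost <- tapply(cohort$cost, batch, mean)
  batch_prev <- tapply(eff, batch, mean)
  ci <- function(x) {
    m <- mean(x)
    se <- stats::sd(x) / sqrt(length(x))
    c(m - 1.96 * se, m + 1.96 * se)
  }
  final_states <- table(factor(cohort$state, levels = STATE_LEVELS))
  structure(list(
    strategy = strategy, n = as.integer(n), seed = seed,
    horizon_age = horizon_age,
    per_capita_cost = mean(cohort$cost),
    cum_t2dm_prev = mean(eff),
    ci_cost = ci(as.numeric(batch_cost)),
    ci_prev = ci(as.numeric(batch_prev)),
    batch_cost = as.numeric(batch_cost),
    batch_prev = as.numeric(batch_prev),
    final_state_dist = as.numeric(final_states) / n,
    state_levels = STATE_LEVELS,
    cycles = cycle
  ), class = "cohort_result")
}

#' Run all three strategies on a common seed
#'
#' @param n Cohort size.
#' @param params A `param_set`.
#' @param strategies Subset of CONTROL/S1/S2.
#' @param ... Passed to [run_cohort()].
#' @return Named list of `cohort_result`s.
#' @export
run_strategies <- function(n, params, strategies = STRATEGY_LEVELS, ...) {
  stats::setNames(
    lapply(strategies, function(s) run_cohort(n, s, params, ...)),
    strategies)
}

#' Deterministic expected-occupancy oracle
#'
#' Computes the exact model expectation of the cumulative T2DM prevalence,
#' the per-capita discounted cost, and the terminal state distribution by a
#' forward recursion of expected state occupancy over (baseline age, sex,
#' exam-goer) strata -- no sampling. The compartment space splits every
#' pre-diabetes substate and T2DM by diagnosis status and tracks dead
#' individuals by whether they ever had T2DM. Used as the independent check
#' on the microsimulation; supports the default accounting options plus the
#' sunk-FPG flag (not the intervention-years cap or effect discounting).
#'
#' @param strategy "CONTROL", "S1" or "S2".
#' @param params A `param_set`.
#' @param life_table A `life_table` (default synthetic).
#' @param demography A [demography_model()].
#' @param horizon_age Terminal age.
#' @param options A [sim_options()] (defaults only, see above).
#' @return List with `cum_t2dm_prev`, `per_capita_cost`, `final_state_dist`
#'   (over NGT, iIFG, iIGT, IFG_IGT, T2DM, DEAD).
#' @export
expected_occupancy <- function(strategy, params, life_table = NULL,
                               demography = demography_model(),
                               horizon_age = 80, options = sim_options()) {
  stopifnot(strategy %in% STRATEGY_LEVELS)
  if (is.finite(options$intervention_years_cap) || options$discount_effects) {
    stopf("expected_occupancy supports only default accounting options")
  }
  if (is.null(life_table)) life_table <- synth_life_table(demography)
  life_mat <- life_table_matrix(life_table)
  v <- function(nm) param_value(params, nm)
  r <- v("discount_rate")
  aic <- annual_intervention_cost(params)
  fpg_unit <- v("fpg_cost")
  cdrs_unit <- v("cdrs_cost")
  ogtt_unit <- v("ogtt_cost")
  compliance <- v("compliance")
  # compartments: NGT, iIFG_u, iIFG_d, iIGT_u, iIGT_d, BOTH_u, BOTH_d,
  #               T2DM_u, T2DM_d, DEAD_no, DEAD_t2dm
  K <- 11L
  UNDIAG <- c(1L, 2L, 4L, 6L, 8L)
  state_of <- c("NGT", "iIFG", "iIFG", "iIGT", "iIGT", "IFG_IGT", "IFG_IGT",
                "T2DM", "T2DM", "DEAD", "DEAD")
  pmf <- age_pmf(demography)
  exam_w <- c(v("exam_rate"), 1 - v("exam_rate"))
  sex_w <- c(M = 1 - demography$female_fraction, F = demography$female_fraction)
  trans_key <- c(iIFG = "iifg", iIGT = "iigt", IFG_IGT = "ifgigt")

  total_prev <- 0
  total_cost <- 0
  total_final <- stats::setNames(numeric(6), STATE_LEVELS)
  for (sex in c("M", "F")) {
    for (exam in c(TRUE, FALSE)) {
      w_group <- sex_w[[sex]] * exam_w[if (exam) 1L else 2L]
      # test offer for this stratum
      if (exam) {
        test <- if (strategy == "S1") "CDRS" else "FPG"
        offer <- 1
      } else {
        test <- "CDRS"
        offer <- if (strategy == "CONTROL") 0 else compliance
      }
      first_unit <- if (test == "CDRS") cdrs_unit else
        if (options$treat_exam_fpg_as_sunk && exam) 0 else fpg_unit
      p_pos <- first_line_positive_prob(
        c("NGT", "iIFG", "iIGT", "IFG_IGT", "T2DM"), test, params)
      names(p_pos) <- c("NGT", "iIFG", "iIGT", "IFG_IGT", "T2DM")
      for (k in seq_len(nrow(pmf))) {
        age0 <- pmf$age[k]
        w <- w_group * pmf$prob[k]
        occ <- numeric(K)
        ip <- initial_state_probs(age0, params)[1, ]
        occ[1] <- ip["NGT"]; occ[2] <- ip["iIFG"]; occ[4] <- ip["iIGT"]
        occ[6] <- ip["IFG_IGT"]; occ[8] <- ip["T2DM"]
        cost <- 0
        for (t in 0:(horizon_age - age0 - 1L)) {
          a <- age0 + t
          disc <- (1 + r)^(-t)
          # screening
          if (offer > 0) {
            for (j in UNDIAG) {
              pp <- p_pos[[state_of[j]]]
              cost <- cost + occ[j] * offer * (first_unit + pp * ogtt_unit) * disc
              if (j > 1L) {  # NGT has no diagnosed compartment
                moved <- occ[j] * offer * pp
                occ[j + 1L] <- occ[j + 1L] + moved
                occ[j] <- occ[j] - moved
              }
            }
          }
          # intervention while diagnosed pre-diabetic
          cost <- cost + (occ[3] + occ[5] + occ[7]) * aic * disc
          # glycemic transitions
          new <- occ
          p_ngt_out <- c(v("trans_ngt_iifg"), v("trans_ngt_iigt"),
                         v("trans_ngt_ifgigt"))
          new[1] <- new[1] - occ[1] * sum(p_ngt_out)
          new[2] <- new[2] + occ[1] * p_ngt_out[1]
          new[4] <- new[4] + occ[1] * p_ngt_out[2]
          new[6] <- new[6] + occ[1] * p_ngt_out[3]
          for (s in PREDM_STATES) {
            key <- trans_key[[s]]
            iu <- c(iIFG = 2L, iIGT = 4L, IFG_IGT = 6L)[[s]]
            p_rev <- v(paste0("trans_", key, "_ngt"))
            pu <- band_lookup(progression_table(params, key, FALSE), a)
            pd <- band_lookup(progression_table(params, key, TRUE), a)
            new[8] <- new[8] + occ[iu] * pu
            new[1] <- new[1] + occ[iu] * p_rev
            new[iu] <- new[iu] - occ[iu] * (pu + p_rev)
            new[9] <- new[9] + occ[iu + 1L] * pd
            new[1] <- new[1] + occ[iu + 1L] * p_rev  # diagnosis cleared
            new[iu + 1L] <- new[iu + 1L] - occ[iu + 1L] * (pd + p_rev)
          }
          occ <- new
          # mortality
          qx <- life_mat[min(a, 100) + 1L, sex]
          dead_t2dm <- (occ[8] + occ[9]) * qx
          dead_other <- sum(occ[1:7]) * qx
          occ[1:9] <- occ[1:9] * (1 - qx)
          occ[10] <- occ[10] + dead_other
          occ[11] <- occ[11] + dead_t2dm
        }
        total_prev <- total_prev + w * (occ[8] + occ[9] + occ[11])
        total_cost <- total_cost + w * cost
        fin <- tapply(occ, state_of, sum)[STATE_LEVELS]
        total_final <- total_final + w * fin
      }
    }
  }
  list(cum_t2dm_prev = total_prev, per_capita_cost = total_cost,
       final_state_dist = total_final)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %s  n=%d  seed=%s\n", x$strategy, x$n,
              format(x$seed)))
  cat(sprintf("  per-capita discounted cost: $%.2f (95%% CI %.2f, %.2f)\n",
              x$per_capita_cost, x$ci_cost[1], x$ci_cost[2]))
  cat(sprintf("  cumulative T2DM prevalence: %.2f%% (95%% CI %.2f, %.2f)\n",
              100 * x$cum_t2dm_prev, 100 * x$ci_prev[1], 100 * x$ci_prev[2]))
  invisible(x)
}
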