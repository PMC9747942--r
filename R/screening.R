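# Screening cascades. Three strategies are compared:
#   CONTROL - status quo: FPG at the annual health examination; no screening
#             for people without an examination.
#   S1      - CDRS questionnaire for everyone (at the exam for exam-goers,
#             self-administered otherwise).
#   S2      - status quo for exam-goers (FPG) plus self-administered CDRS for
#             non-exam-goers.
# A positive first-line test triggers a confirmatory OGTT, taken as the gold
# standard: it reveals the true glycemic state. Compliance scales only the
# self-administered CDRS among non-exam-goers; exam-based testing always
# happens.

#' Simulation accounting options
#'
#' @param treat_exam_fpg_as_sunk If TRUE, FPG performed within a routine
#'   examination is charged at zero (the examination happens regardless);
#'   default FALSE charges the FPG unit cost wherever the strategy uses it.
#' @param intervention_years_cap Charge lifestyle-intervention costs for at
#'   most this many years after a pre-diabetes diagnosis (default `Inf`:
#'   charge every year spent diagnosed pre-diabetic).
#' @param discount_effects If TRUE, also discount the effectiveness outcome;
#'   default FALSE (costs-only discounting).
#' @return A list of class `sim_options`.
#' @export
sim_options <- function(treat_exam_fpg_as_sunk = FALSE,
                        intervention_years_cap = Inf,
                        discount_effects = FALSE) {
  structure(list(
    treat_exam_fpg_as_sunk = isTRUE(treat_exam_fpg_as_sunk),
    intervention_years_cap = intervention_years_cap,
    discount_effects = isTRUE(discount_effects)
  ), class = "sim_options")
}

#' Probability that a first-line test is positive given the true state
#'
#' Maps (glycemic state, test) to the test's operating characteristic: the
#' state-specific sensitivity for diseased states, or the false-positive
#' (misdiagnosis) rate for NGT. CDRS uses one common pre-diabetes
#' sensitivity for all three substates; FPG has substate-specific
#' sensitivities and cannot detect isolated IGT (default 0).
#'
#' @param state Character vector of states (no DEAD).
#' @param test "FPG" or "CDRS" (scalar or vector).
#' @param params A `param_set`.
#' @return Probabilities.
#' @export
first_line_positive_prob <- function(state, test, params) {
  if (length(test) == 1L) test <- rep(test, length(state))
  stopifnot(all(state %in% setdiff(STATE_LEVELS, "DEAD")),
            all(test %in% c("FPG", "CDRS")))
  v <- function(nm) param_value(params, nm)
  p <- numeric(length(state))
  fpg <- test == "FPG"
  p[fpg & state == "T2DM"] <- v("fpg_sens_t2dm")
  p[fpg & state == "iIFG"] <- v("fpg_sens_iifg")
  p[fpg & state == "iIGT"] <- v("fpg_sens_iigt")
  p[fpg & state == "IFG_IGT"] <- v("fpg_sens_ifgigt")
  p[fpg & state == "NGT"] <- v("fpg_fp_ngt")
  p[!fpg & state == "T2DM"] <- v("cdrs_sens_t2dm")
  p[!fpg & state %in% PREDM_STATES] <- v("cdrs_sens_prediab")
  p[!fpg & state == "NGT"] <- v("cdrs_fp_ngt")
  p
}

# Vectorized test assignment for eligible individuals. u_offer is the
# compliance draw (used only for self-administered CDRS).
offered_test_vec <- function(exam_goer, strategy, params, u_offer) {
  compliance <- param_value(params, "compliance")
  test <- rep("NONE", length(exam_goer))
  if (strategy == "CONTROL") {
    test[exam_goer] <- "FPG"
  } else if (strategy == "S1") {
    test[exam_goer] <- "CDRS"
    test[!exam_goer & u_offer < compliance] <- "CDRS"
  } else if (strategy == "S2") {
    test[exam_goer] <- "FPG"
    test[!exam_goer & u_offer < compliance] <- "CDRS"
  } else {
    stopf("unknown strategy '%s'", strategy)
  }
  test
}

#' Which first-line test an individual is offered this year
#'
#' CONTROL: FPG for exam-goers, nothing otherwise. S1: CDRS for everyone
#' (self-administered CDRS among non-exam-goers happens with probability
#' `compliance`). S2: FPG for exam-goers, self-administered CDRS with
#' probability `compliance` otherwise.
#'
#' @param individual One-row `cohort` (or list) with fields `alive`,
#'   `diagnosed`, `exam_goer`.
#' @param strategy "CONTROL", "S1" or "S2".
#' @param params A `param_set`.
#' @param rng A uniform draw in [0,1) for the compliance decision (default:
#'   drawn from the session RNG).
#' @return "FPG", "CDRS" or "NONE".
#' @export
offered_test <- function(individual, strategy, params, rng = stats::runif(1)) {
  if (!isTRUE(individual$alive) || isTRUE(individual$diagnosed)) {
    stopf("offered_test: individual must be alive and undiagnosed")
  }
  offered_test_vec(isTRUE(individual$exam_goer), strategy, params, rng[1])
}

#' Run one screening pass for one individual
#'
#' First-line test per [offered_test()]; a positive result triggers an OGTT
#' which reveals the true state. True pre-diabetes becomes a pre-DM
#' diagnosis (lifestyle intervention starts this cycle), true T2DM becomes a
#' T2DM diagnosis (leaves the screening pool for good), a false-positive NGT
#' returns to the pool. The event cost is the sum of unit costs of tests
#' actually performed (CDRS costs nothing by default), undiscounted.
#'
#' @param individual One-row `cohort` or list with `state`, `alive`,
#'   `diagnosed`, `exam_goer`.
#' @param strategy "CONTROL", "S1" or "S2".
#' @param params A `param_set`.
#' @param rng Two uniform draws (compliance, test result); default from the
#'   session RNG.
#' @param options A [sim_options()].
#' @return List: `first_line_test`, `first_line_positive`, `ogtt_done`,
#'   `new_diagnosis` ("none"/"preDM"/"T2DM"), `cost`.
#' @export
screen_once <- function(individual, strategy, params,
                        rng = stats::runif(2), options = sim_options()) {
  test <- offered_test(individual, strategy, params, rng[1])
  out <- list(first_line_test = test, first_line_positive = FALSE,
              ogtt_done = FALSE, new_diagnosis = "none", cost = 0)
  if (test == "NONE") return(out)
  first_cost <- if (test == "CDRS") {
    param_value(params, "cdrs_cost")
  } else if (options$treat_exam_fpg_as_sunk && isTRUE(individual$exam_goer)) {
    0
  } else {
    param_value(params, "fpg_cost")
  }
  out$cost <- first_cost
  p_pos <- first_line_positive_prob(individual$state, test, params)
  if (rng[2] < p_pos) {
    out$first_line_positive <- TRUE
    out$ogtt_done <- TRUE
    out$cost <- out$cost + param_value(params, "ogtt_cost")
    if (individual$state %in% PREDM_STATES) {
      out$new_diagnosis <- "preDM"
    } else if (individual$state == "T2DM") {
      out$new_diagnosis <- "T2DM"
    }
  }
  out
}

#' Annual lifestyle-intervention cost
#'
#' Unit intervention cost times the number of sessions per year (default
#' twice yearly), charged for each year an individual spends in a diagnosed
#' pre-diabetes state.
#'
#' @param params A `param_set`.
#' @return USD per person-year of diagnosed pre-diabetes.
#' @export
annual_intervention_cost <- function(params) {
  param_value(params, "interventions_per_year") *
    param_value(params, "intervention_cost")
}

# Vectorized one-cycle screening pass over a whole cohort. Returns per-person
# undiscounted screening cost and the new-diagnosis vector.
screen_cycle <- function(cohort, strategy, params, u_offer, u_first, options) {
  n <- nrow(cohort)
  cost <- numeric(n)
  new_diag <- rep("none", n)
  eligible <- cohort$alive & !cohort$diagnosed
  if (!any(eligible)) return(list(cost = cost, new_diagnosis = new_diag))
  test <- rep("NONE", n)
  test[eligible] <- offered_test_vec(cohort$exam_goer[eligible], strategy,
                                     params, u_offer[eligible])
  tested <- test != "NONE"
  if (!any(tested)) return(list(cost = cost, new_diagnosis = new_diag))
  fpg_unit <- param_value(params, "fpg_cost")
  cdrs_unit <- param_value(params, "cdrs_cost")
  first_cost <- ifelse(test[tested] == "CDRS", cdrs_unit,
                       ifelse(options$treat_exam_fpg_as_sunk &
                                cohort$exam_goer[tested], 0, fpg_unit))
  p_pos <- first_line_positive_prob(cohort$state[tested], test[tested], params)
  pos <- u_first[tested] < p_pos
  cost[tested] <- first_cost + pos * param_value(params, "ogtt_cost")
  st <- cohort$state[tested]
  nd <- rep("none", sum(tested))
  nd[pos & st %in% PREDM_STATES] <- "preDM"
  nd[pos & st == "T2DM"] <- "T2DM"
  new_diag[tested] <- nd
  list(cost = cost, new_diagnosis = new_diag)
}
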