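# Cohort initialization: each simulated adult gets an age and sex from the
# demography model, an initial glycemic state drawn from the age-banded
# prevalences of *undiagnosed* disease (nobody starts with a diagnosis), and
# a persistent annual-health-examination flag.

#' Initial-state probabilities at a given age
#'
#' Categorical distribution over {T2DM, iIFG, iIGT, IFG_IGT, NGT} from the
#' age-banded prevalences of undiagnosed disease; NGT takes the remainder.
#'
#' @param age Age(s) in years, >= 18.
#' @param params A `param_set`.
#' @return Matrix with one row per age and columns T2DM, iIFG, iIGT,
#'   IFG_IGT, NGT.
#' @export
initial_state_probs <- function(age, params) {
  p_t2dm <- band_lookup(prevalence_table(params, "t2dm"), age)
  p_iifg <- band_lookup(prevalence_table(params, "iifg"), age)
  p_iigt <- band_lookup(prevalence_table(params, "iigt"), age)
  p_both <- band_lookup(prevalence_table(params, "ifgigt"), age)
  p_ngt <- 1 - (p_t2dm + p_iifg + p_iigt + p_both)
  cbind(T2DM = p_t2dm, iIFG = p_iifg, iIGT = p_iigt,
        IFG_IGT = p_both, NGT = p_ngt)
}

#' Draw an initial glycemic state
#'
#' @param age Age(s) in years.
#' @param params A `param_set`.
#' @param rng Uniform draws in [0,1), one per age (supply `runif(n)` or a
#'   common-random-number stream).
#' @return Character vector of states.
#' @export
assign_initial_state <- function(age, params, rng) {
  pm <- initial_state_probs(age, params)
  cm <- t(apply(pm, 1L, cumsum))
  idx <- rowSums(rng > cm[, 1:4, drop = FALSE]) + 1L
  colnames(pm)[idx]
}

#' Draw the persistent exam-goer flag
#'
#' Bernoulli with the annual-health-examination participation rate; the flag
#' is a lifetime trait (the population is partitioned into with/without
#' annual examination groups, not re-randomized each year).
#'
#' @param params A `param_set`.
#' @param rng Uniform draws in [0,1).
#' @return Logical vector.
#' @export
assign_exam_goer <- function(params, rng) {
  rng < param_value(params, "exam_rate")
}

#' Build a simulation cohort
#'
#' @param n Cohort size, >= 1.
#' @param params A `param_set`.
#' @param demography A [demography_model()].
#' @param seed Integer seed; the same seed yields the identical cohort, so
#'   strategies sharing a seed start from the same people.
#' @return data.frame (class `cohort`) with columns id, age, sex, state,
#'   diagnosed, exam_goer, alive, cost, ever_t2dm, years_intervened.
#' @export
build_cohort <- function(n, params, demography = demography_model(),
                         seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stopf("build_cohort: n must be >= 1")
  }
  n <- as.integer(n)
  demo <- sample_initial_age_sex(n, demography, seed = stream_seed(seed, 0L, 1L))
  u_state <- channel_runif(n, seed, 0L, 2L)
  u_exam <- channel_runif(n, seed, 0L, 3L)
  state <- assign_initial_state(demo$age, params, u_state)
  out <- data.frame(
    id = seq_len(n),
    age = demo$age,
    sex = demo$sex,
    state = state,
    diagnosed = FALSE,
    exam_goer = assign_exam_goer(params, u_exam),
    alive = TRUE,
    cost = 0,
    ever_t2dm = state == "T2DM",
    years_intervened = 0L,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort", "data.frame")
  out
}

#' Write a cohort snapshot to CSV
#'
#' @param cohort A `cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(
    as.data.frame(cohort)[, c("id", "age", "sex", "state", "exam_goer")],
    path, row.names = FALSE)
  invisible(path)
}
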