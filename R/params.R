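# Parameter registry: every model input (prevalences, test operating
# characteristics, annual transition probabilities, unit costs, discounting,
# compliance) as a flat set of scalar entries, each carrying a base value, an
# uncertainty range and a distribution tag for probabilistic sensitivity
# analysis. Age-varying quantities are stored one scalar per age band and
# assembled into age-band tables on demand, so single-parameter perturbation
# (one-way sensitivity analysis) touches exactly one scalar.

STATE_LEVELS <- c("NGT", "iIFG", "iIGT", "IFG_IGT", "T2DM", "DEAD")
PREDM_STATES <- c("iIFG", "iIGT", "IFG_IGT")
STRATEGY_LEVELS <- c("CONTROL", "S1", "S2")

PREV_BAND_LO <- c(18, 40, 60)
PREV_BAND_HI <- c(40, 60, Inf)
PREV_BAND_SUFFIX <- c("lt40", "40_60", "gt60")

TRANS_BAND_LO <- c(18, 40, 50, 60)
TRANS_BAND_HI <- c(40, 50, 60, Inf)
TRANS_BAND_SUFFIX <- c("lt40", "40_50", "50_60", "gt60")

# name / kind / dist for every registered scalar. kind drives bound checks:
# prob in [0,1], cost >= 0, count >= 0.
param_registry <- function() {
  reg <- list(
    c("exam_rate", "prob", "uniform"),
    c("fpg_sens_t2dm", "prob", "beta"),
    c("fpg_sens_iifg", "prob", "beta"),
    c("fpg_sens_iigt", "prob", "fixed"),
    c("fpg_sens_ifgigt", "prob", "beta"),
    c("fpg_fp_ngt", "prob", "uniform"),
    c("cdrs_sens_t2dm", "prob", "beta"),
    c("cdrs_sens_prediab", "prob", "beta"),
    c("cdrs_fp_ngt", "prob", "beta"),
    c("trans_ngt_iifg", "prob", "beta"),
    c("trans_ngt_iigt", "prob", "beta"),
    c("trans_ngt_ifgigt", "prob", "beta"),
    c("trans_iifg_ngt", "prob", "beta"),
    c("trans_iigt_ngt", "prob", "beta"),
    c("trans_ifgigt_ngt", "prob", "beta"),
    c("fpg_cost", "cost", "lognormal"),
    c("ogtt_cost", "cost", "lognormal"),
    c("intervention_cost", "cost", "lognormal"),
    c("cdrs_cost", "cost", "fixed"),
    c("interventions_per_year", "count", "fixed"),
    c("discount_rate", "prob", "uniform"),
    c("wtp", "cost", "fixed"),
    c("compliance", "prob", "fixed")
  )
  for (st in c("t2dm", "iifg", "iigt", "ifgigt")) {
    for (sfx in PREV_BAND_SUFFIX) {
      reg[[length(reg) + 1L]] <- c(paste0("prev_", st, "_", sfx), "prob", "beta")
    }
  }
  for (st in c("iifg", "iigt", "ifgigt")) {
    for (dg in c("undiag", "diag")) {
      for (sfx in TRANS_BAND_SUFFIX) {
        reg[[length(reg) + 1L]] <-
          c(paste0("trans_", st, "_t2dm_", dg, "_", sfx), "prob", "beta")
      }
    }
  }
  out <- data.frame(
    name = vapply(reg, `[`, "", 1L),
    kind = vapply(reg, `[`, "", 2L),
    dist = vapply(reg, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- out$name
  out
}

#' Convert a cumulative probability to an annual probability
#'
#' Converts a probability accumulated over `horizon` years into the constant
#' annual probability that reproduces it, via the standard constant-rate
#' identity `P = 1 - (1 - Pt)^(1/t)` (equivalently `1 - exp(log(1 - Pt)/t)`).
#' Used at parameter-load time so that every rate inside the model is a
#' per-year probability.
#'
#' @param cumulative_prob Probability accumulated over the horizon, in [0, 1).
#' @param horizon Accumulation period in years, > 0.
#' @return The annual probability, in [0, 1). Vectorized over both arguments.
#' @examples
#' annual_probability(0.18155, 3) # ~0.0646
#' @export
annual_probability <- function(cumulative_prob, horizon) {
  if (!is.numeric(cumulative_prob) || !is.numeric(horizon)) {
    stopf("annual_probability: numeric inputs required")
  }
  if (any(is.na(cumulative_prob)) || any(cumulative_prob < 0) ||
      any(cumulative_prob >= 1)) {
    stopf("annual_probability: cumulative_prob must lie in [0, 1)")
  }
  if (any(is.na(horizon)) || any(horizon <= 0)) {
    stopf("annual_probability: horizon must be > 0")
  }
  1 - (1 - cumulative_prob)^(1 / horizon)
}

#' Age-band probability table
#'
#' An ordered set of contiguous half-open age bands `[min_age, max_age)`
#' covering all adult ages, each holding one probability. A boundary age
#' belongs to the upper band (so a table printed as "<40, 40-60, >60" maps
#' age 40 to the middle band and age 60 to the top band).
#'
#' @param min_age,max_age Numeric vectors of band edges; bands must be
#'   contiguous, start at 18 and end at Inf.
#' @param value One probability per band.
#' @return An object of class `age_band_table`.
#' @export
age_band_table <- function(min_age, max_age, value) {
  if (length(min_age) != length(max_age) || length(min_age) != length(value)) {
    stopf("age_band_table: min_age, max_age, value must have equal length")
  }
  if (min_age[1] != 18) stopf("age_band_table: bands must start at age 18")
  if (!is.infinite(max_age[length(max_age)])) {
    stopf("age_band_table: last band must be open-ended (max_age = Inf)")
  }
  if (length(min_age) > 1 &&
      !all(min_age[-1] == max_age[-length(max_age)])) {
    stopf("age_band_table: bands must be contiguous and non-overlapping")
  }
  if (any(min_age >= max_age)) stopf("age_band_table: empty band")
  if (!all(is_prob(value))) stopf("age_band_table: values must lie in [0, 1]")
  structure(list(min_age = min_age, max_age = max_age, value = value),
            class = "age_band_table")
}

#' Look up the probability for an age in an age-band table
#'
#' @param table An [age_band_table()].
#' @param age Age(s) in years, >= 18.
#' @return The band value(s) containing each age.
#' @export
band_lookup <- function(table, age) {
  stopifnot(inherits(table, "age_band_table"))
  if (any(is.na(age)) || any(age < 18)) {
    stopf("band_lookup: age must be >= 18")
  }
  idx <- findInterval(age, table$min_age)
  table$value[idx]
}

default_params_path <- function() {
  system.file("extdata", "params_default.json", package = "prediabsim",
              mustWork = TRUE)
}

#' Load a parameter document
#'
#' Reads a JSON parameter document (one key per registered input, each an
#' object `{base, low, high, dist}`; `low`/`high`/`dist` optional), validates
#' every entry and the cross-field structural invariants, and returns a
#' `param_set`. A missing range defaults to 75--125% of the base value
#' (clamped to [0, 1] for probabilities); a missing distribution tag falls
#' back to the registry default for that field.
#'
#' @param source Path to a JSON file, or a named list with the same shape.
#' @return A validated `param_set`.
#' @seealso [default_params()], [perturb()]
#' @export
load_params <- function(source) {
  doc <- if (is.character(source) && length(source) == 1L) {
    jsonlite::read_json(source, simplifyVector = FALSE)
  } else if (is.list(source)) {
    source
  } else {
    stopf("load_params: source must be a file path or a named list")
  }
  reg <- param_registry()
  unknown <- setdiff(names(doc), reg$name)
  if (length(unknown) > 0) {
    stopf("load_params: unknown field(s): %s", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(reg$name, names(doc))
  if (length(missing) > 0) {
    stopf("load_params: missing field(s): %s", paste(missing, collapse = ", "))
  }
  fields <- list()
  for (nm in reg$name) {
    entry <- doc[[nm]]
    if (is.numeric(entry) && length(entry) == 1L) entry <- list(base = entry)
    if (is.null(entry$base)) stopf("load_params: field '%s' has no base", nm)
    base <- as.numeric(entry$base)
    kind <- reg[nm, "kind"]
    low <- if (is.null(entry$low)) NA_real_ else as.numeric(entry$low)
    high <- if (is.null(entry$high)) NA_real_ else as.numeric(entry$high)
    if (is.na(low) || is.na(high)) {
      # default variation range: 75-125% of base
      low <- 0.75 * base
      high <- 1.25 * base
      if (kind == "prob") high <- min(1, high)
    }
    dist <- if (is.null(entry$dist)) reg[nm, "dist"] else as.character(entry$dist)
    if (!dist %in% c("beta", "lognormal", "uniform", "fixed")) {
      stopf("load_params: field '%s' has unknown distribution '%s'", nm, dist)
    }
    fields[[nm]] <- list(base = base, low = low, high = high, dist = dist)
  }
  params <- structure(list(fields = fields), class = "param_set")
  validate_param_set(params)
  params
}

#' Default parameter set
#'
#' The parameter file shipped with the package: age-banded prevalences of
#' undiagnosed T2DM and the three pre-diabetes substates, FPG/CDRS operating
#' characteristics, annual glycemic transition probabilities (diagnosis- and
#' age-dependent for progression to T2DM), unit costs in 2021 USD, a 5%/yr
#' discount rate, a $12,551 willingness-to-pay threshold and full screening
#' compliance.
#'
#' @return A validated `param_set`.
#' @export
default_params <- function() {
  load_params(default_params_path())
}

#' Read a scalar parameter's base value
#'
#' @param params A `param_set`.
#' @param field Registered field name.
#' @return The base value.
#' @export
param_value <- function(params, field) {
  stopifnot(inherits(params, "param_set"))
  if (!field %in% names(params$fields)) {
    stopf("param_value: unknown field '%s'", field)
  }
  params$fields[[field]]$base
}

param_range <- function(params, field) {
  e <- params$fields[[field]]
  c(e$low, e$high)
}

#' Perturb one scalar parameter
#'
#' Returns a copy of `params` with the base value of one registered scalar
#' replaced and all invariants re-checked; the input object is untouched. If
#' the new value falls outside the stored uncertainty range (e.g. a tripled
#' cost in a one-way scenario) the range is widened to include it.
#'
#' @param params A `param_set`.
#' @param field_path Registered field name.
#' @param value New base value.
#' @return A new validated `param_set`.
#' @export
perturb <- function(params, field_path, value) {
  stopifnot(inherits(params, "param_set"))
  if (!field_path %in% names(params$fields)) {
    stopf("perturb: unknown field '%s'", field_path)
  }
  check_scalar_number(value, "perturb: value")
  out <- params
  out$fields[[field_path]]$base <- value
  out$fields[[field_path]]$low <- min(out$fields[[field_path]]$low, value)
  out$fields[[field_path]]$high <- max(out$fields[[field_path]]$high, value)
  validate_param_set(out)
  out
}

#' Validate a parameter set
#'
#' Checks per-field bounds (probabilities in [0,1], costs and counts
#' non-negative, low <= base <= high) and the structural invariants: within
#' every age band the initial-state prevalences must sum to < 1 (the
#' remainder is NGT), and for every (substate, diagnosis status, age band)
#' the outgoing transition probabilities must sum to <= 1.
#'
#' @param params A `param_set`.
#' @return `params`, invisibly; errors name the offending field.
#' @export
validate_param_set <- function(params) {
  stopifnot(inherits(params, "param_set"))
  reg <- param_registry()
  for (nm in reg$name) {
    e <- params$fields[[nm]]
    if (is.null(e)) stopf("validate: missing field '%s'", nm)
    for (part in c("base", "low", "high")) {
      if (!is.numeric(e[[part]]) || length(e[[part]]) != 1L || is.na(e[[part]])) {
        stopf("validate: field '%s' has invalid %s", nm, part)
      }
    }
    if (e$low > e$base || e$base > e$high) {
      stopf("validate: field '%s' violates low <= base <= high", nm)
    }
    kind <- reg[nm, "kind"]
    if (kind == "prob" && !(all(is_prob(c(e$base, e$low, e$high))))) {
      stopf("validate: field '%s' must lie in [0, 1]", nm)
    }
    if (kind %in% c("cost", "count") && any(c(e$base, e$low) < 0)) {
      stopf("validate: field '%s' must be non-negative", nm)
    }
  }
  v <- function(nm) params$fields[[nm]]$base
  for (sfx in PREV_BAND_SUFFIX) {
    tot <- v(paste0("prev_t2dm_", sfx)) + v(paste0("prev_iifg_", sfx)) +
      v(paste0("prev_iigt_", sfx)) + v(paste0("prev_ifgigt_", sfx))
    if (tot >= 1) {
      stopf("validate: prevalences in band '%s' sum to %.4f (must be < 1)",
            sfx, tot)
    }
  }
  ngt_out <- v("trans_ngt_iifg") + v("trans_ngt_iigt") + v("trans_ngt_ifgigt")
  if (ngt_out > 1) stopf("validate: NGT outgoing probabilities sum to > 1")
  for (st in c("iifg", "iigt", "ifgigt")) {
    revert <- v(paste0("trans_", st, "_ngt"))
    for (dg in c("undiag", "diag")) {
      for (sfx in TRANS_BAND_SUFFIX) {
        p <- v(paste0("trans_", st, "_t2dm_", dg, "_", sfx))
        if (p + revert > 1) {
          stopf("validate: outgoing probabilities for %s/%s band %s sum to > 1",
                st, dg, sfx)
        }
      }
    }
  }
  invisible(params)
}

# Assemble the age-band prevalence table for one initial state.
# state: one of "t2dm", "iifg", "iigt", "ifgigt".
prevalence_table <- function(params, state) {
  vals <- vapply(PREV_BAND_SUFFIX, function(sfx) {
    params$fields[[paste0("prev_", state, "_", sfx)]]$base
  }, 0.0)
  age_band_table(PREV_BAND_LO, PREV_BAND_HI, unname(vals))
}

# Assemble the age-band pre-DM -> T2DM progression table.
progression_table <- function(params, substate, diagnosed) {
  dg <- if (diagnosed) "diag" else "undiag"
  vals <- vapply(TRANS_BAND_SUFFIX, function(sfx) {
    params$fields[[paste0("trans_", substate, "_t2dm_", dg, "_", sfx)]]$base
  }, 0.0)
  age_band_table(TRANS_BAND_LO, TRANS_BAND_HI, unname(vals))
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set>", length(x$fields), "registered scalars\n")
  cat("  exam_rate:", x$fields$exam_rate$base,
      " discount_rate:", x$fields$discount_rate$base,
      " compliance:", x$fields$compliance$base, "\n")
  cat("  costs (FPG/OGTT/intervention):",
      x$fields$fpg_cost$base, "/", x$fields$ogtt_cost$base, "/",
      x$fields$intervention_cost$base, "USD\n")
  invisible(x)
}
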