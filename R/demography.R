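# Synthetic demography: a Gompertz-Makeham life table standing in for the
# national all-cause mortality table, and a truncated-normal age sampler
# matching the published adult age structure (mean age 45.70, 48.92% female).
# Users holding the real yearbook table can substitute it via
# load_life_table() without touching the rest of the pipeline.

#' Demography model
#'
#' Parameters of the synthetic population: a truncated-normal age
#' distribution (ages floored to whole years) and a Gompertz-Makeham
#' mortality hazard `mu(a) = makeham_c + b_sex * exp(theta * a)` with
#' sex-specific scale. The latent normal location is solved numerically at
#' construction so that the *expected floored, truncated* age equals
#' `mean_age` exactly; defaults are calibrated so that synthetic life
#' expectancy at birth is about 74 y (male) and 80 y (female).
#'
#' @param mean_age Target mean of sampled (integer) ages, years.
#' @param age_sd Latent normal SD, years.
#' @param age_min,age_max Support of sampled ages, `[age_min, age_max)`.
#' @param female_fraction Probability a sampled individual is female.
#' @param makeham_c Age-independent hazard floor, per year.
#' @param gompertz_b_male,gompertz_b_female Sex-specific Gompertz scale.
#' @param gompertz_theta Log-hazard slope, per year of age.
#' @return An object of class `demography_model`.
#' @export
demography_model <- function(mean_age = 45.70, age_sd = 16,
                             age_min = 18, age_max = 80,
                             female_fraction = 0.4892,
                             makeham_c = 5e-4,
                             gompertz_b_male = 5.834e-5,
                             gompertz_b_female = 3.291e-5,
                             gompertz_theta = 0.09) {
  if (!(age_min >= 18 && age_min < age_max && age_max <= 100)) {
    stopf("demography_model: need 18 <= age_min < age_max <= 100")
  }
  if (!is_prob(female_fraction)) {
    stopf("demography_model: female_fraction must lie in [0, 1]")
  }
  if (any(c(makeham_c, gompertz_b_male, gompertz_b_female,
            gompertz_theta) <= 0)) {
    stopf("demography_model: hazard parameters must be > 0")
  }
  if (age_sd <= 0) stopf("demography_model: age_sd must be > 0")
  m <- structure(list(
    mean_age = mean_age, age_sd = age_sd,
    age_min = age_min, age_max = age_max,
    female_fraction = female_fraction,
    makeham_c = makeham_c,
    gompertz_b_male = gompertz_b_male,
    gompertz_b_female = gompertz_b_female,
    gompertz_theta = gompertz_theta
  ), class = "demography_model")
  m$latent_mean <- solve_latent_mean(m)
  m
}

# Expected value of floor(X) for X ~ Normal(mu, sd) truncated to [lo, hi).
floored_trunc_mean <- function(mu, sd, lo, hi) {
  k <- lo:(hi - 1)
  z <- stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd)
  p <- (stats::pnorm(k + 1, mu, sd) - stats::pnorm(k, mu, sd)) / z
  sum(k * p)
}

solve_latent_mean <- function(model) {
  f <- function(mu) {
    floored_trunc_mean(mu, model$age_sd, model$age_min, model$age_max) -
      model$mean_age
  }
  stats::uniroot(f, lower = model$age_min - 20,
                 upper = model$age_max + 20, tol = 1e-10)$root
}

# Exact pmf of the sampled integer ages under the model (used by the
# deterministic expectation oracle and by cohort-composition tests).
age_pmf <- function(model) {
  k <- model$age_min:(model$age_max - 1)
  z <- stats::pnorm(model$age_max, model$latent_mean, model$age_sd) -
    stats::pnorm(model$age_min, model$latent_mean, model$age_sd)
  p <- (stats::pnorm(k + 1, model$latent_mean, model$age_sd) -
          stats::pnorm(k, model$latent_mean, model$age_sd)) / z
  data.frame(age = k, prob = p)
}

#' Generate a synthetic life table
#'
#' Annual death probabilities `qx(a, sex) = min(1, c + b_sex * exp(theta*a))`
#' for integer ages 0--100 and both sexes, with `qx(100, .) = 1` so the table
#' is closed. With the default calibration, life expectancy at birth is about
#' 74 y (male) and 80 y (female), bracketing the 80-year model horizon used
#' as the average Chinese life expectancy.
#'
#' @param model A [demography_model()].
#' @return A `life_table`: data.frame with columns `age`, `sex` ("M"/"F"),
#'   `qx`.
#' @export
synth_life_table <- function(model = demography_model()) {
  stopifnot(inherits(model, "demography_model"))
  ages <- 0:100
  qx_of <- function(b) {
    q <- pmin(1, model$makeham_c + b * exp(model$gompertz_theta * ages))
    q[ages == 100] <- 1
    q
  }
  out <- rbind(
    data.frame(age = ages, sex = "M", qx = qx_of(model$gompertz_b_male)),
    data.frame(age = ages, sex = "F", qx = qx_of(model$gompertz_b_female))
  )
  validate_life_table(out)
}

validate_life_table <- function(df) {
  need <- c("age", "sex", "qx")
  if (!all(need %in% names(df))) {
    stopf("life table must have columns age, sex, qx")
  }
  df$sex <- as.character(df$sex)
  if (!all(df$sex %in% c("M", "F"))) {
    stopf("life table: sex must be 'M' or 'F'")
  }
  full <- expand.grid(age = 0:100, sex = c("M", "F"),
                      stringsAsFactors = FALSE)
  key <- paste(df$age, df$sex)
  gaps <- full[!paste(full$age, full$sex) %in% key, , drop = FALSE]
  if (nrow(gaps) > 0) {
    stopf("life table: missing cells: %s",
          paste(sprintf("(%d, %s)", gaps$age, gaps$sex), collapse = ", "))
  }
  if (anyDuplicated(key)) stopf("life table: duplicated (age, sex) cells")
  if (!all(is_prob(df$qx))) stopf("life table: qx must lie in [0, 1]")
  if (!all(df$qx[df$age == 100] == 1)) {
    stopf("life table: qx at age 100 must be 1")
  }
  df <- df[order(df$sex, df$age), c("age", "sex", "qx")]
  rownames(df) <- NULL
  class(df) <- c("life_table", "data.frame")
  df
}

#' Load a life table from CSV
#'
#' Expects columns `age` (integer 0--100), `sex` ("M"/"F"), `qx`; every
#' (age, sex) cell must be present and `qx(100, .)` must equal 1. Use this to
#' substitute a real yearbook life table for the synthetic default.
#'
#' @param path CSV file path.
#' @return A validated `life_table`.
#' @export
load_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(df)
}

#' Write a life table to CSV
#'
#' @param life_table A `life_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(as.data.frame(life_table), path, row.names = FALSE)
  invisible(path)
}

# Fast qx lookup: matrix [age 0..100, sex M/F].
life_table_matrix <- function(life_table) {
  m <- matrix(NA_real_, nrow = 101, ncol = 2, dimnames = list(NULL, c("M", "F")))
  m[life_table$age + 1L, ] <- NA_real_
  m[cbind(life_table$age + 1L, match(life_table$sex, c("M", "F")))] <- life_table$qx
  m
}

#' Life expectancy at birth from a life table
#'
#' Discrete survivorship sum: `e0 = sum_{a>=1} l(a) + 0.5`, with
#' `l(a+1) = l(a) * (1 - qx(a))`. Serves as an independent check on the
#' synthetic mortality calibration.
#'
#' @param life_table A `life_table`.
#' @param sex "M" or "F".
#' @return Years.
#' @export
life_expectancy <- function(life_table, sex) {
  qx <- life_table$qx[life_table$sex == sex][order(life_table$age[life_table$sex == sex])]
  l <- cumprod(1 - qx)
  sum(l) + 0.5
}

#' Sample initial ages and sexes
#'
#' Ages: normal(latent mean, `age_sd`) truncated to `[age_min, age_max)` by
#' inverse-CDF sampling, floored to whole years. Sexes: Bernoulli draws with
#' probability `female_fraction` of "F". Deterministic for a fixed seed; the
#' caller's RNG state is untouched.
#'
#' @param n Number of individuals, >= 1.
#' @param model A [demography_model()].
#' @param seed Integer seed.
#' @return data.frame with columns `age` (integer), `sex` ("M"/"F").
#' @export
sample_initial_age_sex <- function(n, model = demography_model(), seed = 1L) {
  stopifnot(inherits(model, "demography_model"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stopf("sample_initial_age_sex: n must be >= 1")
  }
  n <- as.integer(n)
  with_seed(seed, {
    plo <- stats::pnorm(model$age_min, model$latent_mean, model$age_sd)
    phi <- stats::pnorm(model$age_max, model$latent_mean, model$age_sd)
    u <- stats::runif(n, plo, phi)
    age <- floor(stats::qnorm(u, model$latent_mean, model$age_sd))
    age <- pmin(pmax(age, model$age_min), model$age_max - 1L)
    sex <- ifelse(stats::runif(n) < model$female_fraction, "F", "M")
    data.frame(age = as.integer(age), sex = sex, stringsAsFactors = FALSE)
  })
}

#' @export
print.demography_model <- function(x, ...) {
  cat("<demography_model> mean age", x$mean_age, "(latent",
      round(x$latent_mean, 2), "), SD", x$age_sd,
      ", support [", x$age_min, ",", x$age_max, "), female fraction",
      x$female_fraction, "\n")
  invisible(x)
}
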