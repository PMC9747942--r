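# Sensitivity analyses: one-way (tornado) scans over each parameter's
# uncertainty range, compliance-rate scans, and probabilistic sensitivity
# analysis (PSA) with joint resampling of every uncertain parameter --
# beta for probabilities (moment-matched), lognormal for costs, uniform for
# range-only quantities -- plus cost-effectiveness acceptability curves.

#' Simulation configuration for sensitivity runs
#'
#' Bundles the scale and pairing of the repeated simulations that sensitivity
#' analyses perform. All runs within an analysis share `seed` (common random
#' numbers), so differences are attributable to the parameter being varied.
#'
#' @param n Cohort size per run.
#' @param seed Integer seed.
#' @param demography A [demography_model()].
#' @param life_table A `life_table` (default: synthetic from `demography`).
#' @param horizon_age Terminal age.
#' @param options A [sim_options()].
#' @param comparison Character pair `c(comparator, reference)` for the
#'   headline ICER (default S1 vs CONTROL).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 10000, seed = 1L,
                       demography = demography_model(),
                       life_table = NULL, horizon_age = 80,
                       options = sim_options(),
                       comparison = c("S1", "CONTROL")) {
  if (is.null(life_table)) life_table <- synth_life_table(demography)
  stopifnot(all(comparison %in% STRATEGY_LEVELS), length(comparison) == 2L)
  structure(list(n = as.integer(n), seed = seed, demography = demography,
                 life_table = life_table, horizon_age = horizon_age,
                 options = options, comparison = comparison),
            class = "sim_config")
}

run_pair <- function(params, config, strategies) {
  run_strategies(config$n, params, strategies,
                 life_table = config$life_table,
                 demography = config$demography, seed = config$seed,
                 horizon_age = config$horizon_age, options = config$options)
}

headline_icer <- function(params, config) {
  res <- run_pair(params, config, unique(c(config$comparison)))
  icer(res[[config$comparison[2]]], res[[config$comparison[1]]],
       wtp = param_value(params, "wtp"))$icer
}

#' One-way sensitivity analysis for one parameter
#'
#' Reruns the paired simulation with the parameter at its low and at its high
#' range end (everything else at base, same seeds) and reports the headline
#' ICER at both ends and the spread.
#'
#' @param field_path Registered scalar with a (low, high) range.
#' @param params A `param_set`.
#' @param config A [sim_config()].
#' @return A `tornado_entry` list: `field_path`, `low_value`, `high_value`,
#'   `icer_at_low`, `icer_at_high`, `spread`.
#' @export
one_way <- function(field_path, params, config = sim_config()) {
  if (!field_path %in% names(params$fields)) {
    stopf("one_way: unknown field '%s'", field_path)
  }
  rng <- param_range(params, field_path)
  lo <- headline_icer(perturb(params, field_path, rng[1]), config)
  hi <- headline_icer(perturb(params, field_path, rng[2]), config)
  structure(list(field_path = field_path,
                 low_value = rng[1], high_value = rng[2],
                 icer_at_low = lo, icer_at_high = hi,
                 spread = abs(hi - lo)),
            class = "tornado_entry")
}

#' Tornado analysis over many parameters
#'
#' @param params A `param_set`.
#' @param config A [sim_config()].
#' @param fields Fields to scan (default: every registered scalar with a
#'   non-degenerate range).
#' @return data.frame sorted by decreasing spread (rank 1 = most influential).
#' @export
tornado <- function(params, config = sim_config(), fields = NULL) {
  if (is.null(fields)) {
    fields <- names(Filter(function(e) e$high > e$low, params$fields))
    fields <- setdiff(fields, c("wtp", "compliance"))
  }
  rows <- lapply(fields, function(f) {
    e <- one_way(f, params, config)
    data.frame(field = f, low = e$low_value, high = e$high_value,
               icer_low = e$icer_at_low, icer_high = e$icer_at_high,
               spread = e$spread)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Compliance-rate scan
#'
#' Reruns the full paired three-arm comparison at each self-screening
#' compliance rate. The control arm has no self-administered component, so
#' its results are identical across rates (same seed).
#'
#' @param rates Compliance rates in [0, 1].
#' @param params A `param_set`.
#' @param config A [sim_config()].
#' @return data.frame: rate, strategy, cost, prev, and per-rate ICER columns
#'   (vs control; S1 vs S2).
#' @export
compliance_scan <- function(rates, params, config = sim_config()) {
  stopifnot(all(is_prob(rates)))
  rows <- list()
  for (rate in rates) {
    p <- perturb(params, "compliance", rate)
    res <- run_pair(p, config, STRATEGY_LEVELS)
    wtp <- param_value(p, "wtp")
    ic1 <- icer(res$CONTROL, res$S1, wtp)$icer
    ic2 <- icer(res$CONTROL, res$S2, wtp)$icer
    ic12 <- icer(res$S2, res$S1, wtp)$icer
    for (s in STRATEGY_LEVELS) {
      rows[[length(rows) + 1L]] <- data.frame(
        rate = rate, strategy = s,
        cost = res[[s]]$per_capita_cost,
        prev = res[[s]]$cum_t2dm_prev,
        icer_vs_control = switch(s, CONTROL = NA_real_, S1 = ic1, S2 = ic2),
        icer_s1_vs_s2 = if (s == "S1") ic12 else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a sampling distribution to a (mean, range) summary
#'
#' The range is read as a central 95% interval, `SD = (high - low)/3.92`.
#' Beta: moment matching `alpha = m(m(1-m)/s^2 - 1)`, `beta = alpha(1-m)/m`
#' (mean-unbiased). Lognormal: moment matching on the natural scale
#' (`sdlog^2 = log(1 + s^2/m^2)`, `meanlog = log(m) - sdlog^2/2`), also
#' mean-unbiased. Uniform: the range is used directly as hard bounds (its
#' mean is the midpoint). `fixed` always returns the mean.
#'
#' @param family "beta", "lognormal", "uniform" or "fixed".
#' @param mean Base value.
#' @param low,high Range ends.
#' @return A `dist_spec` with the fitted internal parameters.
#' @export
fit_distribution <- function(family, mean, low, high) {
  stopifnot(family %in% c("beta", "lognormal", "uniform", "fixed"))
  spec <- list(family = family, mean = mean, low = low, high = high)
  s <- (high - low) / 3.92
  if (family == "beta") {
    if (!(mean > 0 && mean < 1)) stopf("beta requires mean in (0, 1)")
    if (s <= 0) stopf("beta requires a non-degenerate range")
    if (s^2 >= mean * (1 - mean)) {
      stopf("beta moments infeasible (SD^2 >= m(1-m)); shrink the range")
    }
    spec$alpha <- mean * (mean * (1 - mean) / s^2 - 1)
    spec$beta <- spec$alpha * (1 - mean) / mean
  } else if (family == "lognormal") {
    if (mean <= 0) stopf("lognormal requires mean > 0")
    if (s <= 0) stopf("lognormal requires a non-degenerate range")
    spec$sdlog <- sqrt(log(1 + s^2 / mean^2))
    spec$meanlog <- log(mean) - spec$sdlog^2 / 2
  } else if (family == "uniform") {
    if (low > high) stopf("uniform requires low <= high")
  }
  structure(spec, class = "dist_spec")
}

#' Sample from a fitted distribution
#'
#' @param spec A `dist_spec` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector; beta/uniform draws respect [low, high] supports
#'   ([0,1] for beta), lognormal draws are > 0.
#' @export
sample_distribution <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
         beta = stats::rbeta(n, spec$alpha, spec$beta),
         lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
         uniform = stats::runif(n, spec$low, spec$high),
         fixed = rep(spec$mean, n))
}

#' Fitted PSA distributions for every uncertain parameter
#'
#' @param params A `param_set`.
#' @return Named list of `dist_spec`s (fields tagged `fixed`, plus the WTP
#'   threshold and the compliance rate, are excluded -- compliance is scanned
#'   separately, not resampled).
#' @export
psa_distributions <- function(params) {
  fields <- setdiff(names(params$fields), c("wtp", "compliance"))
  specs <- list()
  for (nm in fields) {
    e <- params$fields[[nm]]
    if (e$dist == "fixed" || e$high <= e$low) next
    specs[[nm]] <- fit_distribution(e$dist, e$base, e$low, e$high)
  }
  specs
}

set_bases <- function(params, values) {
  for (nm in names(values)) {
    params$fields[[nm]]$base <- values[[nm]]
    params$fields[[nm]]$low <- min(params$fields[[nm]]$low, values[[nm]])
    params$fields[[nm]]$high <- max(params$fields[[nm]]$high, values[[nm]])
  }
  params
}

#' Probabilistic sensitivity analysis
#'
#' Per iteration: jointly resample every uncertain parameter from its fitted
#' distribution (independent draws), rerun the paired three-arm simulation at
#' the configured per-iteration cohort size, and record costs, prevalences
#' and pairwise ICERs. A joint draw violating a structural invariant (e.g.
#' transition probabilities summing past 1) is rejected and redrawn, with the
#' rejection counted. Deterministic for a fixed seed.
#'
#' @param params A `param_set`.
#' @param n_iter Iterations (the reference analysis uses 1,000; scale down
#'   for quick checks).
#' @param config A [sim_config()]; `config$n` is the per-iteration cohort
#'   size.
#' @param seed Integer seed for both parameter draws and simulations.
#' @return A `psa_result`: `draws` (matrix of sampled parameters),
#'   `outcomes` (per-iteration per-strategy cost/prevalence), `icers`
#'   (per-iteration pairwise), `summary` with `p_cost_effective` per
#'   comparison at the base WTP, and `n_rejected`.
#' @export
psa <- function(params, n_iter = 1000, config = sim_config(), seed = 1L) {
  stopifnot(n_iter >= 1)
  specs <- psa_distributions(params)
  wtp <- param_value(params, "wtp")
  draw_names <- names(specs)
  draws <- matrix(NA_real_, nrow = n_iter, ncol = length(draw_names),
                  dimnames = list(NULL, draw_names))
  outcomes <- list()
  icers <- list()
  n_rejected <- 0L
  comparisons <- list(c("S1", "CONTROL"), c("S2", "CONTROL"), c("S1", "S2"))
  for (i in seq_len(n_iter)) {
    p_i <- NULL
    for (try in 1:100) {
      vals <- with_seed(stream_seed(seed, i, 900L + try), {
        vapply(specs, function(sp) sample_distribution(sp, 1L), 0.0)
      })
      cand <- set_bases(params, vals)
      ok <- tryCatch({ validate_param_set(cand); TRUE },
                     error = function(e) FALSE)
      if (ok) { p_i <- cand; draws[i, ] <- vals; break }
      n_rejected <- n_rejected + 1L
    }
    if (is.null(p_i)) stopf("psa: could not find a feasible draw at iteration %d", i)
    it_config <- config
    it_config$seed <- stream_seed(seed, i, 800L)
    res <- run_pair(p_i, it_config, STRATEGY_LEVELS)
    for (s in STRATEGY_LEVELS) {
      outcomes[[length(outcomes) + 1L]] <- data.frame(
        iter = i, strategy = s, cost = res[[s]]$per_capita_cost,
        prev = res[[s]]$cum_t2dm_prev)
    }
    for (cmp in comparisons) {
      ic <- icer(res[[cmp[2]]], res[[cmp[1]]], wtp)
      icers[[length(icers) + 1L]] <- data.frame(
        iter = i, comparator = cmp[1], reference = cmp[2],
        delta_cost = ic$delta_cost, delta_prev = ic$delta_prev,
        icer = ic$icer, cost_effective = ic$cost_effective)
    }
  }
  icers <- do.call(rbind, icers)
  p_ce <- stats::aggregate(cost_effective ~ comparator + reference,
                           data = icers, FUN = mean)
  structure(list(
    draws = draws,
    outcomes = do.call(rbind, outcomes),
    icers = icers,
    summary = list(p_cost_effective = p_ce, wtp = wtp),
    n_rejected = n_rejected, n_iter = n_iter, seed = seed
  ), class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' For each WTP value on the grid, the fraction of PSA iterations in which
#' the comparator is cost-effective against the reference by the net-benefit
#' rule `wtp * delta_prev - delta_cost >= 0`.
#'
#' @param psa_result A `psa_result`.
#' @param wtp_grid WTP values, USD.
#' @return data.frame: wtp, comparator, reference, p_cost_effective.
#' @export
ceac <- function(psa_result, wtp_grid = seq(0, 2000, by = 100)) {
  stopifnot(inherits(psa_result, "psa_result"))
  ic <- psa_result$icers
  rows <- list()
  for (w in wtp_grid) {
    agg <- stats::aggregate(
      I(w * ic$delta_prev - ic$delta_cost >= 0) ~ comparator + reference,
      data = cbind(ic), FUN = mean)
    names(agg)[3] <- "p_cost_effective"
    agg$wtp <- w
    rows[[length(rows) + 1L]] <- agg[, c("wtp", "comparator", "reference",
                                         "p_cost_effective")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations, %d rejected draws\n",
              x$n_iter, x$n_rejected))
  print(x$summary$p_cost_effective)
  invisible(x)
}
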