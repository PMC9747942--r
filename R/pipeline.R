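# Configuration-driven front end: one call runs the base-case three-arm
# comparison (and optionally the compliance scan, tornado and PSA) and writes
# reproducible CSV/JSON artifacts plus a manifest, so any output can be
# regenerated bit-identically from the config alone. An optparse wrapper
# lives at inst/scripts/run_model.R.

#' Build and validate a run configuration
#'
#' @param n_individuals Cohort size, >= 1.
#' @param seed Integer seed.
#' @param horizon_age Terminal age, <= 100.
#' @param strategies Non-empty subset of CONTROL/S1/S2.
#' @param parameter_file Path to a JSON parameter document (default: the
#'   shipped Table-1 file).
#' @param life_table Path to a life-table CSV, or "synthetic".
#' @param output_dir Directory for artifacts (created if absent).
#' @param options A [sim_options()] (accounting flags).
#' @param compliance_rates If non-NULL, run a compliance scan at these rates.
#' @param tornado_fields If non-NULL, run a one-way scan over these fields.
#' @param psa_iterations If > 0, run a PSA with this many iterations.
#' @param psa_cohort_size Per-iteration PSA cohort size.
#' @param write_fixtures If TRUE, also emit the synthetic life table and a
#'   small frozen cohort snapshot.
#' @return A validated `run_config`.
#' @export
run_config <- function(n_individuals, seed = 1L, horizon_age = 80,
                       strategies = STRATEGY_LEVELS,
                       parameter_file = NULL,
                       life_table = "synthetic",
                       output_dir = tempfile("prediabsim_run_"),
                       options = sim_options(),
                       compliance_rates = NULL,
                       tornado_fields = NULL,
                       psa_iterations = 0,
                       psa_cohort_size = 10000,
                       write_fixtures = FALSE) {
  if (!is.numeric(n_individuals) || n_individuals < 1) {
    stopf("run_config: n_individuals must be >= 1")
  }
  if (horizon_age > 100) stopf("run_config: horizon_age must be <= 100")
  if (length(strategies) < 1 || !all(strategies %in% STRATEGY_LEVELS)) {
    stopf("run_config: strategies must be a non-empty subset of %s",
          paste(STRATEGY_LEVELS, collapse = "/"))
  }
  if (is.null(parameter_file)) parameter_file <- default_params_path()
  structure(list(
    n_individuals = as.integer(n_individuals), seed = seed,
    horizon_age = horizon_age, strategies = strategies,
    parameter_file = parameter_file, life_table = life_table,
    output_dir = output_dir, options = options,
    compliance_rates = compliance_rates, tornado_fields = tornado_fields,
    psa_iterations = psa_iterations, psa_cohort_size = psa_cohort_size,
    write_fixtures = isTRUE(write_fixtures)
  ), class = "run_config")
}

write_num_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 12, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Run the configured analysis and write artifacts
#'
#' Writes `results.csv` (per-strategy cost and prevalence with CIs and
#' pairwise ICERs), optionally `compliance.csv`, `tornado.csv`, `psa.csv`
#' and `ceac.csv`, and `manifest.json` (seed, n, parameter-file MD5, package
#' version). Outputs contain no timestamps, so rerunning the same config
#' yields byte-identical files. On failure, partially written outputs are
#' removed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the written file paths and in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  params <- load_params(config$parameter_file)
  demography <- demography_model()
  life_table <- if (identical(config$life_table, "synthetic")) {
    synth_life_table(demography)
  } else {
    load_life_table(config$life_table)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  out <- tryCatch({
    res <- run_strategies(config$n_individuals, params,
                          strategies = config$strategies,
                          life_table = life_table, demography = demography,
                          seed = config$seed,
                          horizon_age = config$horizon_age,
                          options = config$options)
    tab <- icer_table(res, wtp = param_value(params, "wtp"))
    f <- file.path(config$output_dir, "results.csv")
    write_num_csv(tab, f); written <- c(written, f)

    cfg <- sim_config(n = config$n_individuals, seed = config$seed,
                      demography = demography, life_table = life_table,
                      horizon_age = config$horizon_age,
                      options = config$options)
    extras <- list()
    if (!is.null(config$compliance_rates)) {
      cs <- compliance_scan(config$compliance_rates, params, cfg)
      f <- file.path(config$output_dir, "compliance.csv")
      write_num_csv(cs, f); written <- c(written, f)
      extras$compliance <- cs
    }
    if (!is.null(config$tornado_fields)) {
      tn <- tornado(params, cfg, fields = config$tornado_fields)
      f <- file.path(config$output_dir, "tornado.csv")
      write_num_csv(tn, f); written <- c(written, f)
      extras$tornado <- tn
    }
    if (config$psa_iterations > 0) {
      psa_cfg <- cfg
      psa_cfg$n <- as.integer(config$psa_cohort_size)
      ps <- psa(params, n_iter = config$psa_iterations, config = psa_cfg,
                seed = config$seed)
      f <- file.path(config$output_dir, "psa.csv")
      write_num_csv(cbind(iter = ps$icers$iter,
                          comparator = ps$icers$comparator,
                          reference = ps$icers$reference,
                          ps$icers[, c("delta_cost", "delta_prev", "icer")]),
                    f)
      written <- c(written, f)
      cc <- ceac(ps)
      f <- file.path(config$output_dir, "ceac.csv")
      write_num_csv(cc, f); written <- c(written, f)
      extras$psa <- ps
    }
    if (config$write_fixtures) {
      f <- file.path(config$output_dir, "life_table.csv")
      write_life_table(life_table, f); written <- c(written, f)
      f <- file.path(config$output_dir, "cohort_snapshot.csv")
      write_cohort_csv(build_cohort(min(1000L, config$n_individuals), params,
                                    demography, config$seed), f)
      written <- c(written, f)
    }
    manifest <- list(
      package = "prediabsim",
      version = as.character(utils::packageVersion("prediabsim")),
      seed = config$seed, n_individuals = config$n_individuals,
      horizon_age = config$horizon_age, strategies = config$strategies,
      parameter_file_md5 = unname(tools::md5sum(config$parameter_file)),
      life_table = if (identical(config$life_table, "synthetic"))
        "synthetic" else unname(tools::md5sum(config$life_table)),
      accounting = list(
        treat_exam_fpg_as_sunk = config$options$treat_exam_fpg_as_sunk,
        intervention_years_cap = config$options$intervention_years_cap,
        discount_effects = config$options$discount_effects)
    )
    f <- file.path(config$output_dir, "manifest.json")
    jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, f)
    c(list(results = res, table = tab, files = written), extras)
  }, error = on_fail)
  invisible(out)
}
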