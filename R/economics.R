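# Cost accounting and cost-effectiveness arithmetic: discounting, the
# incremental cost-effectiveness ratio (USD per T2DM case prevented), batch
# percentile CIs for the ratio, and the willingness-to-pay decision rule.

#' Discount a cost to present value
#'
#' `amount / (1 + rate)^year_index`; year 0 is undiscounted.
#'
#' @param amount USD.
#' @param year_index Integer year offset, >= 0.
#' @param rate Annual discount rate, >= 0 (base case 5%/yr).
#' @return Discounted USD. Vectorized.
#' @export
discount <- function(amount, year_index, rate) {
  if (any(year_index < 0)) stopf("discount: year_index must be >= 0")
  if (any(rate < 0)) stopf("discount: rate must be >= 0")
  amount / (1 + rate)^year_index
}

#' Incremental cost-effectiveness ratio between two strategies
#'
#' `ICER = (cost_comparator - cost_reference) /
#'         (prev_reference - prev_comparator)`: dollars spent per T2DM case
#' prevented by the comparator relative to the reference. The CI is the
#' percentile interval of per-batch ICERs over the paired cohort batches
#' (both runs must use the same n and seed). A comparator that is cheaper
#' and more effective (or costlier and less effective) is flagged dominant
#' (dominated) and the ratio sign is not meaningful; equal effectiveness
#' flags the ratio undefined.
#'
#' @param reference A `cohort_result` (e.g. the control arm).
#' @param comparator A `cohort_result`.
#' @param wtp Willingness-to-pay threshold, USD per case prevented.
#' @return An `icer_result` list: `delta_cost`, `delta_prev`, `icer`, `ci`,
#'   `undefined`, `dominant`, `dominated`, `cost_effective`.
#' @export
icer <- function(reference, comparator,
                 wtp = param_value(default_params(), "wtp")) {
  stopifnot(inherits(reference, "cohort_result"),
            inherits(comparator, "cohort_result"))
  if (reference$n != comparator$n || !identical(reference$seed, comparator$seed)) {
    stopf("icer: runs must be paired (same n and seed)")
  }
  delta_cost <- comparator$per_capita_cost - reference$per_capita_cost
  delta_prev <- reference$cum_t2dm_prev - comparator$cum_t2dm_prev
  undefined <- delta_prev == 0
  value <- if (undefined) NA_real_ else delta_cost / delta_prev
  dominant <- !undefined && delta_prev > 0 && delta_cost <= 0
  dominated <- !undefined && delta_prev < 0 && delta_cost > 0
  if (dominated) {
    warning("comparator is dominated (costlier and less effective); ",
            "ICER sign is not meaningful", call. = FALSE)
  }
  ci <- c(NA_real_, NA_real_)
  b_dc <- comparator$batch_cost - reference$batch_cost
  b_dp <- reference$batch_prev - comparator$batch_prev
  ok <- b_dp != 0
  if (sum(ok) >= 10) {
    ci <- unname(stats::quantile(b_dc[ok] / b_dp[ok], c(0.025, 0.975)))
  }
  structure(list(
    reference = reference$strategy, comparator = comparator$strategy,
    delta_cost = delta_cost, delta_prev = delta_prev,
    icer = value, ci = ci, undefined = undefined,
    dominant = dominant, dominated = dominated,
    wtp = wtp,
    cost_effective = dominant ||
      (!undefined && !dominated && wtp_decision(value, wtp))
  ), class = "icer_result")
}

#' Willingness-to-pay decision
#'
#' TRUE iff the ICER does not exceed the threshold (inclusive comparison).
#'
#' @param icer_value USD per case prevented (finite).
#' @param wtp Threshold, USD.
#' @return Logical.
#' @export
wtp_decision <- function(icer_value, wtp) {
  if (any(!is.finite(icer_value))) stopf("wtp_decision: icer must be finite")
  icer_value <= wtp
}

#' Tabulate costs, prevalences and pairwise ICERs for a set of runs
#'
#' Mirrors the layout of a strategy-comparison results table: one column per
#' strategy with per-capita cost and cumulative prevalence (with CIs), plus
#' cost per case prevented vs the control and between the two screening
#' strategies.
#'
#' @param results Named list of `cohort_result`s (from [run_strategies()]).
#' @param wtp Willingness-to-pay threshold.
#' @return data.frame, one row per (quantity, strategy) cell.
#' @export
icer_table <- function(results, wtp = param_value(default_params(), "wtp")) {
  rows <- list()
  for (nm in names(results)) {
    r <- results[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = "cost", strategy = nm, value = r$per_capita_cost,
      ci_lo = r$ci_cost[1], ci_hi = r$ci_cost[2])
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = "cum_t2dm_prev_pct", strategy = nm,
      value = 100 * r$cum_t2dm_prev,
      ci_lo = 100 * r$ci_prev[1], ci_hi = 100 * r$ci_prev[2])
  }
  pairs <- list(c("CONTROL", "S1"), c("CONTROL", "S2"), c("S2", "S1"))
  for (p in pairs) {
    if (all(p %in% names(results))) {
      ic <- icer(results[[p[1]]], results[[p[2]]], wtp)
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = sprintf("icer_%s_vs_%s", p[2], p[1]), strategy = p[2],
        value = ic$icer, ci_lo = ic$ci[1], ci_hi = ic$ci[2])
    }
  }
  do.call(rbind, rows)
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("<icer_result> %s vs %s\n", x$comparator, x$reference))
  if (x$undefined) {
    cat("  undefined: no difference in cases prevented\n")
  } else {
    cat(sprintf("  delta cost $%.3f, delta prevalence %.4f => $%.2f per case prevented\n",
                x$delta_cost, x$delta_prev, x$icer))
    if (!any(is.na(x$ci))) {
      cat(sprintf("  95%% CI (%.2f, %.2f)\n", x$ci[1], x$ci[2]))
    }
    cat(sprintf("  %s at WTP $%s\n",
                if (x$cost_effective) "cost-effective" else "NOT cost-effective",
                format(x$wtp)))
  }
  invisible(x)
}
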