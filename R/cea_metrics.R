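# Incremental cost-effectiveness metrics for the two-arm comparison,
# scaled once here to the cohort ("per 1000 hospitalised patients").

#' Incremental cost of the intervention
#'
#' Intervention (active laboratory) cost minus comparator (no testing)
#' cost; negative values mean the intervention is cost-saving.
#'
#' @param cost_intervention,cost_comparator Costs in USD (same cohort scale).
#' @return USD.
#' @export
incremental_cost <- function(cost_intervention, cost_comparator) {
  cost_intervention - cost_comparator
}

#' DALYs averted by the intervention
#'
#' Comparator DALYs minus intervention DALYs; positive values mean the
#' intervention averts disease burden.
#'
#' @param daly_comparator,daly_intervention DALYs (same cohort scale).
#' @return Years.
#' @export
dalys_averted <- function(daly_comparator, daly_intervention) {
  daly_comparator - daly_intervention
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Classifies the (incremental cost, DALYs averted) pair on the
#' cost-effectiveness plane. When the intervention is cheaper and more
#' effective it *dominates* and no finite ratio is reported; when costlier
#' and less effective it is *dominated*. Otherwise the ratio
#' `delta_cost / dalys_averted` is returned, flagged `southwest` when both
#' quantities are negative (cheaper but less effective, where a *lower*
#' ratio favours the comparator). A zero denominator yields an undefined
#' ICER, never infinite arithmetic.
#'
#' @param delta_cost Incremental cost (intervention minus comparator), USD.
#' @param dalys_averted DALYs averted (comparator minus intervention), years.
#' @return A `labcea_icer` list with `label` (one of `"dominant"`,
#'   `"dominated"`, `"icer"`, `"southwest"`, `"undefined"`) and `value`
#'   (the ratio in USD/DALY, or `NA` when no finite ratio is meaningful).
#' @export
icer <- function(delta_cost, dalys_averted) {
  out <- if (dalys_averted == 0) {
    list(label = "undefined", value = NA_real_)
  } else if (delta_cost < 0 && dalys_averted > 0) {
    list(label = "dominant", value = NA_real_)
  } else if (delta_cost > 0 && dalys_averted < 0) {
    list(label = "dominated", value = NA_real_)
  } else if (delta_cost < 0 && dalys_averted < 0) {
    list(label = "southwest", value = delta_cost / dalys_averted)
  } else {
    list(label = "icer", value = delta_cost / dalys_averted)
  }
  structure(out, class = "labcea_icer")
}

#' @export
print.labcea_icer <- function(x, ...) {
  if (x$label == "dominant") {
    cat("Active laboratory dominates (cheaper and more effective)\n")
  } else if (x$label == "dominated") {
    cat("Dominated (costlier and less effective)\n")
  } else if (x$label == "undefined") {
    cat("ICER undefined (zero DALYs averted)\n")
  } else {
    cat(sprintf("ICER $%.2f per DALY averted%s\n", x$value,
                if (x$label == "southwest") " [south-west quadrant]" else ""))
  }
  invisible(x)
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' `wtp * dalys_averted - delta_cost`; positive iff the intervention is
#' cost-effective at that threshold.
#'
#' @inheritParams icer
#' @param wtp Willingness to pay per DALY averted, USD (the study uses $500).
#' @return USD.
#' @export
nmb <- function(delta_cost, dalys_averted, wtp) {
  if (any(wtp < 0)) abort_validation("wtp must be nonnegative")
  wtp * dalys_averted - delta_cost
}

#' Compare the two arms for one regimen
#'
#' Builds and rolls back both strategy trees, converts outcomes to DALYs,
#' and scales to the cohort.
#'
#' @param params A validated `labcea_params` object.
#' @param regimen Empiric regimen name.
#' @param wtp Willingness-to-pay threshold; defaults to the configured
#'   `daly$wtp_per_daly`.
#' @param validate Re-validate `params` before building trees (default).
#' @return A one-row tibble with cohort-scale columns: `regimen`,
#'   `cost_active`, `daly_active`, `cost_none`, `daly_none`, `delta_cost`,
#'   `dalys_averted`, `deaths_averted`, `icer_label`, `icer`, `nmb`.
#' @export
compare_arms <- function(params, regimen, wtp = NULL, validate = TRUE) {
  wtp <- wtp %||% params$daly$wtp_per_daly
  n <- params$daly$cohort_size
  res_a <- rollback(build_strategy_tree(params, "active_lab", regimen, validate))
  res_n <- rollback(build_strategy_tree(params, "no_testing", regimen,
                                        validate = FALSE))
  d_a <- daly_breakdown(res_a, params$daly)
  d_n <- daly_breakdown(res_n, params$daly)
  dc <- incremental_cost(res_a$expected_cost_per_patient * n,
                         res_n$expected_cost_per_patient * n)
  da <- dalys_averted(d_n$daly, d_a$daly)
  ic <- icer(dc, da)
  tibble(regimen = regimen,
         cost_active = res_a$expected_cost_per_patient * n,
         daly_active = d_a$daly,
         cost_none = res_n$expected_cost_per_patient * n,
         daly_none = d_n$daly,
         delta_cost = dc,
         dalys_averted = da,
         deaths_averted = d_n$deaths - d_a$deaths,
         icer_label = ic$label,
         icer = ic$value,
         nmb = nmb(dc, da, wtp))
}

#' Evaluate the full two-arm comparison for each empiric regimen
#'
#' The deterministic headline analysis: one row per regimen with arm-level
#' costs and DALYs per cohort, incremental cost, DALYs and deaths averted,
#' ICER (or dominance label) and net monetary benefit.
#'
#' @inheritParams compare_arms
#' @param regimens Character vector of regimen names; defaults to all three.
#' @return A tibble, one row per regimen (see [compare_arms()]).
#' @examples
#' cea_evaluate(baseline_parameters("adult"))
#' @export
cea_evaluate <- function(params, regimens = names(params$regimens), wtp = NULL) {
  bind_rows(lapply(regimens, function(r) compare_arms(params, r, wtp)))
}
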