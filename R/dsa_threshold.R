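# One-way deterministic sensitivity analysis and break-even threshold
# searches over laboratory cost and volume.

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the full two-arm comparison at each supplied value of one
#' parameter, holding everything else at baseline. The baseline value is
#' always included.
#'
#' @param params A validated `labcea_params` object.
#' @param path Dotted parameter path, e.g. `"test.prevalence"` or
#'   `"costs.icu_cost_per_day"`.
#' @param values Numeric values to test; the baseline value is appended if
#'   absent. Values violating the parameter's invariants abort the scenario.
#' @param regimen Regimen to evaluate (default all three).
#' @param wtp Willingness-to-pay threshold for NMB.
#' @return A tibble, one row per value x regimen: `parameter`, `value`,
#'   `baseline` (logical), `delta_cost`, `dalys_averted`, `deaths_averted`,
#'   `icer_label`, `icer`, `nmb`.
#' @export
one_way <- function(params, path, values, regimen = names(params$regimens),
                    wtp = NULL) {
  assert_valid_parameters(params)
  base_value <- param_get(params, path)
  if (is.null(base_value)) {
    abort_validation(paste0("unknown parameter path: ", path))
  }
  if (!is.numeric(base_value) || length(base_value) != 1) {
    abort_validation(paste0("one_way() varies scalar parameters; ", path,
                            " is not scalar"))
  }
  values <- unique(c(values, base_value))
  rows <- lapply(values, function(v) {
    cand <- param_set(params, path, v)
    viol <- validate_parameters(cand)
    if (nrow(viol) > 0) {
      abort_validation(c(
        sprintf("value %g for %s violates invariants; scenario aborted", v, path),
        setNames(paste0(viol$field, ": ", viol$rule), rep("x", nrow(viol)))))
    }
    cea_evaluate(cand, regimen, wtp) %>%
      mutate(parameter = path, value = v, baseline = v == base_value,
             .before = 1)
  })
  bind_rows(rows) %>%
    select(all_of(c("parameter", "value", "baseline", "regimen", "delta_cost",
                    "dalys_averted", "deaths_averted", "icer_label", "icer",
                    "nmb")))
}

#' Tornado-style multi-parameter sensitivity analysis
#'
#' Runs [one_way()] at low/high values for several parameters and orders
#' the output by the absolute swing in incremental cost.
#'
#' @param params A validated `labcea_params` object.
#' @param scenarios A tibble/data frame with columns `path`, `low`, `high`.
#' @param regimen Single regimen to evaluate.
#' @inheritParams one_way
#' @return A tibble, one row per parameter: `parameter`, `low`, `high`,
#'   `delta_cost_low`, `delta_cost_high`, `swing`, sorted by
#'   decreasing `swing`.
#' @export
tornado <- function(params, scenarios, regimen, wtp = NULL) {
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    res <- one_way(params, sc$path, c(sc$low, sc$high), regimen, wtp)
    tibble(parameter = sc$path, low = sc$low, high = sc$high,
           delta_cost_low = res$delta_cost[res$value == sc$low][1],
           delta_cost_high = res$delta_cost[res$value == sc$high][1])
  })
  bind_rows(rows) %>%
    mutate(swing = abs(.data$delta_cost_high - .data$delta_cost_low)) %>%
    arrange(desc(.data$swing))
}

#' @rdname autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.labcea_tornado <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("delta_cost_low", "delta_cost_high"),
                              names_to = "end", values_to = "delta_cost")
  ggplot2::ggplot(long,
                  ggplot2::aes(y = stats::reorder(.data$parameter, .data$swing),
                               x = .data$delta_cost, group = .data$parameter)) +
    ggplot2::geom_line(linewidth = 4, colour = "grey60") +
    ggplot2::labs(x = "Incremental cost per cohort (USD)", y = NULL,
                  title = "One-way sensitivity (tornado)")
}

# criterion evaluation for the threshold search --------------------------------

.criterion_value <- function(params, variable, x, regimen, criterion, wtp) {
  cand <- switch(
    variable,
    maintenance_per_sample = {
      p <- param_set(params, "costs.maintenance_per_sample", x)
      # keep the derived-quotient invariant from firing during the sweep
      param_set(p, "costs.annual_samples",
                p$costs$annual_fixed_lab_cost / max(x, 1e-9))
    },
    annual_samples = {
      # per-sample maintenance follows the fixed annual cost at each volume
      p <- param_set(params, "costs.annual_samples", x)
      param_set(p, "costs.maintenance_per_sample",
                p$costs$annual_fixed_lab_cost / x)
    },
    abort_validation(paste0("unsupported threshold variable: ", variable)))
  cmp <- compare_arms(cand, regimen, wtp = wtp)
  switch(criterion,
         cost_saving = -cmp$delta_cost,      # > 0 iff cost-saving
         cost_effective_at_wtp = cmp$nmb)    # >= 0 iff cost-effective
}

#' Break-even threshold search over laboratory cost or volume
#'
#' Finds where a criterion (cost-saving, or cost-effective at the
#' willingness-to-pay threshold) flips as the per-sample maintenance cost
#' or the annual sample volume varies. For `annual_samples` the per-sample
#' maintenance cost is recomputed as `annual_fixed_lab_cost / annual_samples`
#' at every step, and the result is reported as the smallest integer volume
#' satisfying the criterion. For `maintenance_per_sample` the search
#' bisects to $0.01.
#'
#' @param params A validated `labcea_params` object.
#' @param variable `"maintenance_per_sample"` or `"annual_samples"`.
#' @param criterion `"cost_saving"` or `"cost_effective_at_wtp"`.
#' @param bounds Length-2 numeric interval to search; the criterion must
#'   differ at the two bounds, otherwise a bracket error is raised with
#'   endpoint diagnostics.
#' @param regimen Regimen to evaluate.
#' @param wtp Willingness-to-pay threshold (defaults to configured value).
#' @param tol Bisection tolerance for cost variables (default $0.01).
#' @return A `labcea_threshold` list: `variable`, `criterion`, `regimen`,
#'   `threshold`, and `bracket` (a tibble with the criterion value just
#'   below and above the threshold, confirming the sign flip).
#' @export
breakeven <- function(params, variable = c("maintenance_per_sample",
                                           "annual_samples"),
                      criterion = c("cost_saving", "cost_effective_at_wtp"),
                      bounds, regimen, wtp = NULL, tol = 0.01) {
  variable <- arg_match(variable)
  criterion <- arg_match(criterion)
  assert_valid_parameters(params)
  wtp <- wtp %||% params$daly$wtp_per_daly
  if (length(bounds) != 2 || bounds[1] >= bounds[2] || any(bounds <= 0)) {
    abort_validation("bounds must be a positive increasing interval")
  }
  f <- function(x) .criterion_value(params, variable, x, regimen, criterion, wtp)
  f_lo <- f(bounds[1]); f_hi <- f(bounds[2])
  if (sign(f_lo >= 0) == sign(f_hi >= 0)) {
    abort_bracket(c(
      "criterion does not flip across the bounds",
      i = sprintf("%s = %g -> criterion %.4f; %s = %g -> criterion %.4f",
                  variable, bounds[1], f_lo, variable, bounds[2], f_hi)))
  }

  if (variable == "annual_samples") {
    # integer search: smallest integer volume satisfying the criterion
    lo <- ceiling(bounds[1]); hi <- floor(bounds[2])
    # criterion is monotone nondecreasing in volume (per-sample cost falls)
    while (hi - lo > 1) {
      mid <- floor((lo + hi) / 2)
      if (f(mid) >= 0) hi <- mid else lo <- mid
    }
    threshold <- as.integer(if (f(lo) >= 0) lo else hi)
    bracket <- tibble(value = c(threshold - 1, threshold),
                      criterion_value = c(f(threshold - 1), f(threshold)),
                      satisfied = criterion_value >= 0)
  } else {
    lo <- bounds[1]; hi <- bounds[2]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (sign(f(mid) >= 0) == sign(f_lo >= 0)) lo <- mid else hi <- mid
    }
    threshold <- (lo + hi) / 2
    bracket <- tibble(value = c(lo, hi),
                      criterion_value = c(f(lo), f(hi)),
                      satisfied = criterion_value >= 0)
  }
  structure(list(variable = variable, criterion = criterion,
                 regimen = regimen, threshold = threshold, wtp = wtp,
                 tol = tol, bracket = bracket),
            class = "labcea_threshold")
}

#' @export
print.labcea_threshold <- function(x, ...) {
  cat(sprintf("<labcea_threshold> %s (%s, %s): %s\n", x$variable, x$criterion,
              x$regimen, format(x$threshold, big.mark = ",")))
  print(x$bracket)
  invisible(x)
}

#' @rdname tidy
#' @exportS3Method generics::tidy
tidy.labcea_threshold <- function(x, ...) {
  tibble(variable = x$variable, criterion = x$criterion, regimen = x$regimen,
         threshold = x$threshold, wtp = x$wtp, tol = x$tol)
}
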