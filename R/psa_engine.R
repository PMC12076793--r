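# Probabilistic sensitivity analysis: distribution assignment by moment
# matching, Monte Carlo evaluation of both arms per draw, and summaries
# (cost-effectiveness plane, acceptability curve).

#' Default uncertainty specification for a parameter set
#'
#' One row per uncertain parameter: multinomial transition nodes get
#' Dirichlet distributions, binary probabilities get beta distributions,
#' and daily care costs get lognormal distributions (avoiding negative
#' draws). Elicited probabilities default to an effective sample size of
#' 30 (moderate elicitation-panel confidence) and care costs to a
#' coefficient of variation of 0.3; both are overridable per row.
#'
#' @param params A validated `labcea_params` object.
#' @param ess Effective sample size for Dirichlet/beta moment matching.
#' @param cost_cv Coefficient of variation for lognormal cost distributions.
#' @return A tibble with columns `path`, `family`, `ess`, `cv`.
#' @export
default_uncertainty <- function(params, ess = 30, cost_cv = 0.3) {
  beta_paths <- c("test.prevalence", "test.sensitivity", "test.false_positive",
                  paste0("regimens.", names(params$regimens), ".coverage"),
                  as.vector(outer(.states, .changes, function(s, ch) {
                    paste0("outcomes.mortality.", s, ".", ch)
                  })))
  dir_paths <- c(paste0("transitions.clinical_change.", .states),
                 paste0("transitions.switch.",
                        c("culture_positive", "clinical_only")))
  ln_paths <- c("costs.icu_cost_per_day", "costs.ward_cost_per_day")
  bind_rows(
    tibble(path = beta_paths, family = "beta", ess = ess, cv = NA_real_),
    tibble(path = dir_paths, family = "dirichlet", ess = ess, cv = NA_real_),
    tibble(path = ln_paths, family = "lognormal", ess = NA_real_, cv = cost_cv))
}

#' Attach probability distributions to uncertain parameters
#'
#' Converts an uncertainty specification into concrete sampling
#' distributions by moment matching around the current parameter values:
#' Dirichlet concentration = mean vector x ess; beta `shape1 = mean x ess`,
#' `shape2 = (1 - mean) x ess`; lognormal log-mean/log-sd matched to the
#' arithmetic mean and coefficient of variation
#' (`sdlog = sqrt(log(1 + cv^2))`, `meanlog = log(mean) - sdlog^2 / 2`).
#' Degenerate means (0 or 1 for beta) collapse to the `fixed` family.
#'
#' @param params A validated `labcea_params` object.
#' @param uncertainty A tibble as returned by [default_uncertainty()];
#'   rows with `family = "fixed"` pass the current value through unchanged.
#' @return A tibble with columns `path`, `family`, `mean` (list column) and
#'   `hyper` (list column of family-specific hyperparameters).
#' @export
assign_distributions <- function(params, uncertainty = default_uncertainty(params)) {
  assert_valid_parameters(params)
  rows <- lapply(seq_len(nrow(uncertainty)), function(i) {
    path <- uncertainty$path[i]
    family <- uncertainty$family[i]
    value <- param_get(params, path)
    if (is.null(value)) {
      abort_validation(paste0("uncertainty entry targets unknown parameter: ", path))
    }
    hyper <- switch(
      family,
      fixed = list(value = value),
      beta = {
        ess <- uncertainty$ess[i]
        if (!is.finite(ess) || ess <= 0) abort_validation(
          paste0("beta ess must be positive for ", path))
        m <- as.numeric(value)
        if (m <= 0 || m >= 1) {
          family <- "fixed"
          list(value = value)
        } else {
          list(shape1 = m * ess, shape2 = (1 - m) * ess)
        }
      },
      dirichlet = {
        ess <- uncertainty$ess[i]
        if (!is.finite(ess) || ess <= 0) abort_validation(
          paste0("dirichlet ess must be positive for ", path))
        list(alpha = unlist(value) * ess)
      },
      lognormal = {
        cv <- uncertainty$cv[i]
        if (!is.finite(cv) || cv <= 0) abort_validation(
          paste0("lognormal cv must be positive for ", path))
        m <- as.numeric(value)
        if (m <= 0) {
          family <- "fixed"
          list(value = value)
        } else {
          sdlog <- sqrt(log(1 + cv^2))
          list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
        }
      },
      abort_validation(paste0("unknown distribution family: ", family)))
    tibble(path = path, family = family, mean = list(value),
           hyper = list(hyper))
  })
  bind_rows(rows)
}

# one Monte Carlo draw from a spec row
.draw_spec <- function(family, mean, hyper) {
  switch(family,
         fixed = mean,
         beta = rbeta(1, hyper$shape1, hyper$shape2),
         lognormal = rlnorm(1, hyper$meanlog, hyper$sdlog),
         dirichlet = {
           g <- rgamma(length(hyper$alpha), shape = hyper$alpha, rate = 1)
           d <- as.list(g / sum(g))
           setNames(d, names(hyper$alpha))
         })
}

.draw_params <- function(params, specs, max_retries = 100L) {
  for (attempt in seq_len(max_retries)) {
    cand <- params
    for (i in seq_len(nrow(specs))) {
      cand <- param_set(cand, specs$path[i],
                        .draw_spec(specs$family[i], specs$mean[[i]],
                                   specs$hyper[[i]]))
    }
    if (nrow(validate_parameters(cand)) == 0) return(cand)
  }
  abort_validation(c("PSA draw kept violating parameter invariants",
                     i = paste0("after ", max_retries, " resampling attempts")))
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws every uncertain parameter from its assigned distribution, rebuilds
#' and rolls back both strategy trees per draw, and records the incremental
#' comparison for each regimen. The study design uses 5000 iterations.
#' Identical seed + configuration gives bitwise-identical output.
#'
#' @param params A validated `labcea_params` object.
#' @param n Number of Monte Carlo iterations.
#' @param seed Integer seed; required for reproducibility.
#' @param specs Distribution specs from [assign_distributions()].
#' @param regimens Regimens to evaluate; defaults to all three.
#' @param wtp Willingness-to-pay threshold used for summary probabilities.
#' @return A `labcea_psa` object holding the per-iteration `draws` tibble
#'   (`iteration`, `regimen`, arm-level costs and DALYs, `delta_cost`,
#'   `dalys_averted`, `deaths_averted`), the deterministic `baseline`
#'   evaluation, `n_iterations`, `seed` and `wtp`.
#' @export
run_psa <- function(params, n = 5000, seed,
                    specs = assign_distributions(params),
                    regimens = names(params$regimens), wtp = NULL) {
  if (missing(seed) || !is.numeric(seed)) {
    abort_validation("run_psa() requires an integer seed")
  }
  if (n < 1) abort_validation("n must be at least 1")
  wtp <- wtp %||% params$daly$wtp_per_daly
  assert_valid_parameters(params)
  set.seed(as.integer(seed))
  draws <- vector("list", n)
  for (it in seq_len(n)) {
    p_it <- .draw_params(params, specs)
    rows <- lapply(regimens, function(r) {
      cmp <- compare_arms(p_it, r, wtp = wtp, validate = FALSE)
      cmp$iteration <- it
      cmp
    })
    draws[[it]] <- bind_rows(rows)
  }
  draws <- bind_rows(draws) %>%
    select(all_of(c("iteration", "regimen", "cost_active", "daly_active",
                    "cost_none", "daly_none", "delta_cost", "dalys_averted",
                    "deaths_averted")))
  structure(list(draws = draws, n_iterations = n, seed = as.integer(seed),
                 wtp = wtp, regimens = regimens,
                 baseline = cea_evaluate(params, regimens, wtp)),
            class = "labcea_psa")
}

#' @export
print.labcea_psa <- function(x, ...) {
  cat("<labcea_psa>", x$n_iterations, "iterations | seed", x$seed,
      "| WTP $", x$wtp, "/DALY\n")
  print(tidy(x))
  invisible(x)
}

# quantiles use linear interpolation between order statistics (type 7),
# pinned for bit-reproducibility; the IQR is the 25th-75th percentile pair
.q <- function(x, p) unname(quantile(x, p, type = 7))

#' @rdname tidy
#' @exportS3Method generics::tidy
tidy.labcea_psa <- function(x, ...) {
  wtp <- x$wtp
  x$draws %>%
    group_by(.data$regimen) %>%
    summarise(
      mean_delta_cost = mean(.data$delta_cost),
      q25_delta_cost = .q(.data$delta_cost, 0.25),
      median_delta_cost = .q(.data$delta_cost, 0.5),
      q75_delta_cost = .q(.data$delta_cost, 0.75),
      mean_dalys_averted = mean(.data$dalys_averted),
      q25_dalys_averted = .q(.data$dalys_averted, 0.25),
      median_dalys_averted = .q(.data$dalys_averted, 0.5),
      q75_dalys_averted = .q(.data$dalys_averted, 0.75),
      mean_deaths_averted = mean(.data$deaths_averted),
      q25_deaths_averted = .q(.data$deaths_averted, 0.25),
      q75_deaths_averted = .q(.data$deaths_averted, 0.75),
      probability_cost_saving = mean(.data$delta_cost < 0),
      probability_cost_effective =
        mean(nmb(.data$delta_cost, .data$dalys_averted, wtp) >= 0),
      .groups = "drop")
}

#' @rdname glance
#' @exportS3Method generics::glance
glance.labcea_psa <- function(x, ...) {
  tibble(n_iterations = x$n_iterations, seed = x$seed, wtp = x$wtp,
         n_regimens = length(x$regimens))
}

#' Cost-effectiveness plane points and quadrant tallies
#'
#' Returns the per-iteration (DALYs averted, incremental cost) points with
#' their cost-effectiveness-plane quadrant (`dominant` is the lower-right:
#' more effective and cost-saving) and whether each point falls below the
#' willingness-to-pay line (i.e. has nonnegative net monetary benefit).
#'
#' @param psa A `labcea_psa` from [run_psa()].
#' @param wtp Willingness-to-pay line; defaults to the PSA's configured value.
#' @return A tibble of points (`iteration`, `regimen`, `dalys_averted`,
#'   `delta_cost`, `quadrant`, `cost_effective`); quadrant tallies and the
#'   fraction below the WTP line per regimen are in
#'   `attr(, "quadrant_tallies")`.
#' @export
ce_plane <- function(psa, wtp = psa$wtp) {
  pts <- psa$draws %>%
    mutate(
      quadrant = dplyr::case_when(
        .data$dalys_averted >= 0 & .data$delta_cost < 0 ~ "dominant",
        .data$dalys_averted >= 0 & .data$delta_cost >= 0 ~ "trade-off",
        .data$dalys_averted < 0 & .data$delta_cost < 0 ~ "south-west",
        TRUE ~ "dominated"),
      cost_effective = nmb(.data$delta_cost, .data$dalys_averted, wtp) >= 0) %>%
    select(all_of(c("iteration", "regimen", "dalys_averted", "delta_cost",
                    "quadrant", "cost_effective")))
  tallies <- pts %>%
    group_by(.data$regimen, .data$quadrant) %>%
    summarise(n = n(), .groups = "drop_last") %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup()
  attr(pts, "quadrant_tallies") <- tallies
  attr(pts, "wtp") <- wtp
  pts
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' nonnegative net monetary benefit.
#'
#' @param psa A `labcea_psa` from [run_psa()].
#' @param wtp_grid Nonnegative WTP values (USD per DALY averted).
#' @return A `labcea_ceac` tibble: `regimen`, `wtp`,
#'   `probability_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 1000, by = 50)) {
  if (length(wtp_grid) == 0 || any(wtp_grid < 0)) {
    abort_validation("wtp_grid must be nonempty and nonnegative")
  }
  out <- tidyr::crossing(psa$draws, wtp = wtp_grid) %>%
    group_by(.data$regimen, .data$wtp) %>%
    summarise(probability_cost_effective =
                mean(nmb(.data$delta_cost, .data$dalys_averted, .data$wtp) >= 0),
              .groups = "drop")
  class(out) <- c("labcea_ceac", class(out))
  out
}

# plots ------------------------------------------------------------------------

#' @rdname autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.labcea_psa <- function(object, wtp = object$wtp, ...) {
  pts <- ce_plane(object, wtp)
  base <- object$baseline
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$dalys_averted,
                                    y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_point(data = base, colour = "red", size = 2) +
    ggplot2::facet_wrap(~regimen, scales = "free") +
    ggplot2::labs(x = "DALYs averted per cohort",
                  y = "Incremental cost per cohort (USD)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("dashed line: WTP $%s per DALY averted", wtp))
}

#' Plot methods for result objects
#'
#' `autoplot()` draws the cost-effectiveness plane for a `labcea_psa`
#' (points below the dashed willingness-to-pay line are cost-effective; the
#' red point is the deterministic base case) and the acceptability curve
#' for a `labcea_ceac`.
#'
#' @param object A `labcea_psa` or `labcea_ceac` object.
#' @param wtp Willingness-to-pay line for the plane plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot
#' @rdname autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.labcea_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp,
                                       y = .data$probability_cost_effective,
                                       colour = .data$regimen)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay per DALY averted (USD)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve")
}
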