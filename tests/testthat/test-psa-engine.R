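test_that("moment matching reproduces the configured means", {
  specs <- assign_distributions(baseline)
  # beta: mean 0.8 at ess 30 -> beta(24, 6)
  sens <- specs[specs$path == "test.sensitivity", ]
  expect_equal(sens$hyper[[1]]$shape1, 0.8 * 30)
  expect_equal(sens$hyper[[1]]$shape2, 0.2 * 30)
  # dirichlet: concentration = mean vector x ess
  cc <- specs[specs$path == "transitions.clinical_change.infected_covered", ]
  expect_equal(unname(cc$hyper[[1]]$alpha),
               unname(unlist(baseline$transitions$clinical_change$infected_covered)) * 30)
  # lognormal: closed-form mean of exp(meanlog + sdlog^2/2) is the target
  icu <- specs[specs$path == "costs.icu_cost_per_day", ]
  expect_equal(exp(icu$hyper[[1]]$meanlog + icu$hyper[[1]]$sdlog^2 / 2),
               baseline$costs$icu_cost_per_day, tolerance = 1e-12)
  expect_error(
    assign_distributions(baseline,
                         tibble::tibble(path = "test.sensitivity",
                                        family = "beta", ess = -1, cv = NA_real_)),
    class = "labcea_validation_error")
})

test_that("sampled distribution means match configured means at n = 50000", {
  n <- 50000
  set.seed(31)
  # beta(0.8, ess 50)
  x <- stats::rbeta(n, 0.8 * 50, 0.2 * 50)
  se <- stats::sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - 0.8), 3 * se)
  # dirichlet (0.5, 0.3, 0.2) x ess 100, componentwise
  alpha <- c(0.5, 0.3, 0.2) * 100
  g <- matrix(stats::rgamma(3 * n, shape = rep(alpha, n)), nrow = 3)
  d <- t(g) / colSums(g)
  for (j in 1:3) {
    se <- stats::sd(d[, j]) / sqrt(n)
    expect_lt(abs(mean(d[, j]) - alpha[j] / 100), 3 * se)
  }
  # lognormal arithmetic mean 100, cv 0.3
  sdlog <- sqrt(log(1 + 0.3^2))
  y <- stats::rlnorm(n, log(100) - sdlog^2 / 2, sdlog)
  se <- stats::sd(y) / sqrt(n)
  expect_lt(abs(mean(y) - 100), 3 * se)
})

test_that("PSA is reproducible under a fixed seed and degenerate when fixed", {
  p1 <- run_psa(baseline, n = 15, seed = 11)
  p2 <- run_psa(baseline, n = 15, seed = 11)
  expect_identical(p1$draws, p2$draws)
  expect_identical(tidy(p1), tidy(p2))
  p3 <- run_psa(baseline, n = 15, seed = 12)
  expect_false(identical(p3$draws, p1$draws))

  # all-fixed families: each iteration equals the deterministic baseline
  fixed_spec <- tibble::tibble(path = c("test.sensitivity",
                                        "costs.icu_cost_per_day"),
                               family = "fixed", ess = NA_real_, cv = NA_real_)
  pf <- run_psa(baseline, n = 3, seed = 5,
                specs = assign_distributions(baseline, fixed_spec))
  det <- cea_evaluate(baseline)
  for (it in 1:3) {
    sub <- pf$draws[pf$draws$iteration == it, ]
    expect_equal(sub$delta_cost, det$delta_cost, tolerance = 1e-12)
    expect_equal(sub$dalys_averted, det$dalys_averted, tolerance = 1e-12)
  }
})

test_that("PSA means shrink to the deterministic result as dispersion vanishes", {
  tight <- assign_distributions(
    baseline, default_uncertainty(baseline, ess = 1e6, cost_cv = 1e-4))
  psa <- run_psa(baseline, n = 60, seed = 21, specs = tight,
                 regimens = "ceftriaxone_gentamicin")
  det <- cea_evaluate(baseline, "ceftriaxone_gentamicin")
  dc <- psa$draws$delta_cost
  se <- stats::sd(dc) / sqrt(length(dc))
  expect_lt(abs(mean(dc) - det$delta_cost), 3 * se)
})

test_that("summary quartiles are ordered and probabilities are proportions", {
  psa <- run_psa(baseline, n = 40, seed = 3)
  s <- tidy(psa)
  expect_true(all(s$q25_delta_cost <= s$median_delta_cost))
  expect_true(all(s$median_delta_cost <= s$q75_delta_cost))
  expect_true(all(s$probability_cost_saving >= 0 &
                    s$probability_cost_saving <= 1))
  g <- glance(psa)
  expect_identical(g$n_iterations, 40)
  expect_identical(g$seed, 3L)
})

test_that("CE plane quadrants and CEAC follow their definitions", {
  psa <- run_psa(baseline, n = 30, seed = 17,
                 regimens = "ampicillin_gentamicin")
  pts <- ce_plane(psa)
  expect_identical(nrow(pts), 30L)
  dom <- pts$quadrant == "dominant"
  expect_identical(dom, pts$dalys_averted >= 0 & pts$delta_cost < 0)
  # fraction below the WTP line equals the acceptability probability
  expect_equal(mean(pts$cost_effective),
               tidy(psa)$probability_cost_effective)
  expect_equal(
    ceac(psa, psa$wtp)$probability_cost_effective,
    mean(pts$cost_effective))

  # two-draw toy: acceptability steps 0 -> 0.5 -> 1 at the two ICERs
  toy <- structure(
    list(draws = tibble::tibble(iteration = 1:2, regimen = "toy",
                                cost_active = 0, daly_active = 0,
                                cost_none = 0, daly_none = 0,
                                delta_cost = c(100, 300),
                                dalys_averted = c(1, 1),
                                deaths_averted = 0),
         n_iterations = 2L, seed = 1L, wtp = 500, regimens = "toy"),
    class = "labcea_psa")
  curve <- ceac(toy, c(0, 99, 100, 299, 300, 400))
  expect_equal(curve$probability_cost_effective, c(0, 0, 0.5, 0.5, 1, 1))
  # at wtp 0 the curve reports the cost-saving fraction
  expect_equal(ceac(psa, 0)$probability_cost_effective,
               mean(psa$draws$delta_cost <= 0))
  expect_error(ceac(psa, numeric(0)), class = "labcea_validation_error")
})

test_that("plots build without evaluation errors", {
  psa <- run_psa(baseline, n = 10, seed = 2,
                 regimens = "ceftriaxone_gentamicin")
  expect_s3_class(ggplot2::ggplot_build(autoplot(psa)), "ggplot_built")
  expect_s3_class(ggplot2::ggplot_build(autoplot(ceac(psa))), "ggplot_built")
})
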