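test_that("one-way analysis at the baseline value reproduces the baseline", {
  res <- one_way(baseline, "test.prevalence", numeric(0),
                 "ceftriaxone_gentamicin")
  expect_identical(nrow(res), 1L)
  expect_true(res$baseline)
  det <- cea_evaluate(baseline, "ceftriaxone_gentamicin")
  expect_equal(res$delta_cost, det$delta_cost)
  expect_equal(res$dalys_averted, det$dalys_averted)

  expect_error(one_way(baseline, "test.prevalence", c(0.2, 1.4)),
               class = "labcea_validation_error")
  expect_error(one_way(baseline, "test.does_not_exist", 0.5),
               class = "labcea_validation_error")
})

test_that("deaths averted increase with the prevalence of true infection", {
  res <- dplyr::arrange(
    one_way(baseline, "test.prevalence", c(0.2, 0.3, 0.5, 0.6),
            "ceftriaxone_gentamicin"), value)
  expect_true(all(diff(res$deaths_averted) > 0))
  expect_true(all(diff(res$dalys_averted) > 0))
})

test_that("doubling the bottle count adds exactly the extra laboratory cost", {
  res <- dplyr::arrange(
    one_way(baseline, "test.bottles_per_patient", 4,
            "ampicillin_gentamicin"), value)
  # the per-bottle expected cost (result-weighted bottle price + maintenance)
  per_bottle <- expected_lab_cost(baseline) / baseline$test$bottles_per_patient
  cohort <- baseline$daly$cohort_size
  expect_equal(res$delta_cost[res$value == 4] - res$delta_cost[res$value == 2],
               2 * per_bottle * cohort, tolerance = 1e-6)
  expect_equal(res$dalys_averted[res$value == 4],
               res$dalys_averted[res$value == 2], tolerance = 1e-9)
  expect_equal(res$deaths_averted[res$value == 4],
               res$deaths_averted[res$value == 2], tolerance = 1e-9)
})

test_that("incremental cost is linear in maintenance with slope bottles x cohort", {
  delta_at <- function(m) {
    p <- param_set(baseline, "costs.maintenance_per_sample", m)
    p <- param_set(p, "costs.annual_fixed_lab_cost", m * p$costs$annual_samples)
    cea_evaluate(p, "ceftriaxone_gentamicin")$delta_cost
  }
  ms <- c(10, 34.53, 76, 120)
  ds <- vapply(ms, delta_at, numeric(1))
  slopes <- diff(ds) / diff(ms)
  expect_equal(slopes,
               rep(baseline$test$bottles_per_patient *
                     baseline$daly$cohort_size, length(slopes)),
               tolerance = 1e-9)
})

test_that("tornado output is ordered by absolute cost swing", {
  scen <- tibble::tibble(
    path = c("test.prevalence", "costs.icu_cost_per_day"),
    low = c(0.2, 250), high = c(0.6, 500))
  tor <- tornado(baseline, scen, "ceftriaxone_gentamicin")
  expect_identical(nrow(tor), 2L)
  expect_true(all(diff(tor$swing) <= 0))
})

test_that("break-even sample volume matches an exhaustive grid scan", {
  th <- breakeven(baseline, "annual_samples", "cost_saving",
                  bounds = c(800, 1600), regimen = "ceftriaxone_gentamicin")
  # oracle: smallest integer volume with negative incremental cost
  delta_at_n <- function(n) {
    p <- param_set(baseline, "costs.annual_samples", n)
    p <- param_set(p, "costs.maintenance_per_sample",
                   p$costs$annual_fixed_lab_cost / n)
    cea_evaluate(p, "ceftriaxone_gentamicin")$delta_cost
  }
  grid <- vapply(800:1600, delta_at_n, numeric(1))
  expect_identical(th$threshold, (800:1600)[which(grid < 0)[1]])
  # bracketing evidence: criterion flips across the integer threshold
  expect_identical(th$bracket$satisfied, c(FALSE, TRUE))
  expect_lt(delta_at_n(th$threshold), 0)
  expect_gt(delta_at_n(th$threshold - 1), 0)
})

test_that("break-even maintenance cost flips the criterion at the threshold", {
  th <- breakeven(baseline, "maintenance_per_sample", "cost_saving",
                  bounds = c(1, 500), regimen = "meropenem_vancomycin")
  expect_lte(th$bracket$value[2] - th$bracket$value[1], 2 * th$tol)
  expect_identical(th$bracket$satisfied, c(TRUE, FALSE))
  # mirror of the deterministic linearity: threshold where delta_cost = 0
  det <- cea_evaluate(baseline, "meropenem_vancomycin")$delta_cost
  slope <- baseline$test$bottles_per_patient * baseline$daly$cohort_size
  predicted <- baseline$costs$maintenance_per_sample - det / slope
  expect_equal(th$threshold, predicted, tolerance = 0.02)
})

test_that("unbracketed criteria raise bracket errors with diagnostics", {
  expect_error(
    breakeven(baseline, "annual_samples", "cost_saving", c(5000, 9000),
              regimen = "ceftriaxone_gentamicin"),
    class = "labcea_bracket_error")
  # a tree with no laboratory usage never flips on laboratory cost
  p0 <- param_set(param_set(baseline, "test.sensitivity", 0),
                  "test.false_positive", 0)
  expect_error(
    breakeven(p0, "maintenance_per_sample", "cost_saving", c(200, 400),
              regimen = "meropenem_vancomycin"),
    class = "labcea_bracket_error")
})
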