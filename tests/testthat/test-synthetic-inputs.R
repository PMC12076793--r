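test_that("elicited summaries map to betas with the PERT mean", {
  b <- elicitation_to_beta(0.5, 0.3, 0.7, weight = 10)
  expect_false(b$point_mass)
  expect_equal(b$shape1 / (b$shape1 + b$shape2), 0.5)

  pm <- elicitation_to_beta(0.8, 0.8, 0.8)
  expect_true(pm$point_mass)
  expect_equal(pm$value, 0.8)

  set.seed(12)
  for (i in 1:100) {
    bounds <- sort(stats::runif(2))
    mode <- stats::runif(1, bounds[1], bounds[2])
    w <- stats::runif(1, 2, 100)
    b <- elicitation_to_beta(mode, bounds[1], bounds[2], w)
    pert_mean <- (bounds[1] + 4 * mode + bounds[2]) / 6
    expect_equal(b$shape1 / (b$shape1 + b$shape2), pert_mean,
                 tolerance = 1e-9)
  }
  expect_error(elicitation_to_beta(0.2, 0.5, 0.9),
               class = "labcea_validation_error")
})

test_that("generated parameter sets are reproducible, valid, and ordered", {
  expect_equal(generate_parameter_set(123), generate_parameter_set(123),
               tolerance = 0)
  expect_false(identical(generate_parameter_set(123),
                         generate_parameter_set(124)))

  for (seed in seq(1, 600, by = 3)) {
    p <- generate_parameter_set(seed)
    expect_identical(nrow(validate_parameters(p)), 0L)
    cov <- sapply(p$regimens, `[[`, "coverage")
    # the broad-spectrum regimen covers more than both narrow regimens
    expect_gt(cov[["meropenem_vancomycin"]],
              max(cov[["ceftriaxone_gentamicin"]],
                  cov[["ampicillin_gentamicin"]]))
    expect_gt(p$costs$icu_cost_per_day, p$costs$ward_cost_per_day)
    cc <- p$transitions$clinical_change
    expect_gt(cc$infected_uncovered$deteriorate, cc$infected_covered$deteriorate)
    m <- p$outcomes$mortality
    for (ch in c("improve", "unchanged", "deteriorate")) {
      expect_gte(m$infected_uncovered[[ch]], m$infected_covered[[ch]])
    }
    expect_gt(m$infected_covered$deteriorate, m$infected_covered$improve)
  }
})

test_that("printed study values are never perturbed by generation", {
  paper_registry <- list(
    "test.prevalence" = 0.40, "test.sensitivity" = 0.80,
    "test.false_positive" = 0.05, "test.bottles_per_patient" = 2,
    "test.empiric_days" = 3,
    "regimens.ceftriaxone_gentamicin.drug_cost_per_day" = 1.76,
    "regimens.ampicillin_gentamicin.drug_cost_per_day" = 3.04,
    "regimens.meropenem_vancomycin.drug_cost_per_day" = 35.16,
    "costs.culture_positive_bottle" = 31.90,
    "costs.culture_negative_bottle" = 5.80,
    "costs.maintenance_per_sample" = 34.53,
    "costs.annual_fixed_lab_cost" = 131697,
    "costs.annual_samples" = 3813,
    "daly.years_lost_per_death" = 11, "daly.disability_weight" = 0.133)
  for (seed in c(5, 50, 500)) {
    p <- generate_parameter_set(seed)
    for (path in names(paper_registry)) {
      expect_identical(labcea:::param_get(p, path), paper_registry[[path]])
    }
    u4 <- generate_parameter_set(seed, "under4")
    expect_identical(u4$daly$years_lost_per_death, 66)
    expect_identical(u4$daly$disability_weight, 0.402)
  }
})

test_that("overrides are applied and re-validated", {
  p <- generate_parameter_set(9, overrides = list("test.prevalence" = 0.6))
  expect_equal(p$test$prevalence, 0.6)
  expect_error(
    generate_parameter_set(9, overrides = list("test.prevalence" = 1.6)),
    class = "labcea_validation_error")
})

test_that("synthetic antibiograms hit their coverage targets", {
  expect_equal(generate_antibiogram(77), generate_antibiogram(77))

  # exact coverage at a target of one
  full <- generate_antibiogram(3, n_isolates = 200,
                               targets = c(meropenem_vancomycin = 1))
  expect_equal(as.numeric(
    regimen_coverage(full, c("meropenem", "vancomycin"))), 1)

  # binomial sampling error at large n
  abg <- generate_antibiogram(11, n_isolates = 10000,
                              targets = c(ceftriaxone_gentamicin = 0.5,
                                          ampicillin_gentamicin = 0.55,
                                          meropenem_vancomycin = 0.85))
  expect_lt(abs(as.numeric(
    regimen_coverage(abg, c("ceftriaxone", "gentamicin"))) - 0.5), 0.015)
  expect_lt(abs(as.numeric(
    regimen_coverage(abg, c("ampicillin", "gentamicin"))) - 0.55), 0.015)
  expect_lt(abs(as.numeric(
    regimen_coverage(abg, c("meropenem", "vancomycin"))) - 0.85), 0.011)

  # error shrinks roughly as 1/sqrt(n) (3-sigma envelope at each size)
  for (n in c(500, 2000, 8000)) {
    a <- generate_antibiogram(21, n_isolates = n,
                              targets = c(meropenem_vancomycin = 0.7))
    err <- abs(as.numeric(regimen_coverage(a, c("meropenem", "vancomycin"))) - 0.7)
    expect_lt(err, 3 * sqrt(0.7 * 0.3 / n))
  }

  expect_error(generate_antibiogram(1, targets = c(meropenem_vancomycin = 1.2)),
               class = "labcea_validation_error")
})
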