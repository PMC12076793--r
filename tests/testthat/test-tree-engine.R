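test_that("rollback matches hand arithmetic on a toy tree", {
  r <- rollback(toy_tree())
  expect_equal(r$expected_cost_per_patient, 15)
  expect_equal(r$expected_deaths_per_patient, 0)
  paths <- enumerate_paths(toy_tree())
  expect_equal(nrow(paths), 2L)
  expect_equal(sort(paths$total_cost), c(10, 20))
  expect_equal(paths$probability, c(0.5, 0.5))

  r2 <- rollback(toy_tree(p1 = 0.3, d1 = 0.1, d2 = 0.5, los1 = 2, los2 = 8))
  expect_equal(r2$expected_deaths_per_patient, 0.3 * 0.1 + 0.7 * 0.5)
  expect_equal(r2$expected_los_days_per_patient, 0.3 * 2 + 0.7 * 8)
})

test_that("tree structure follows the arm definition", {
  ta <- build_strategy_tree(baseline, "active_lab", "ceftriaxone_gentamicin")
  # first chance node under the decision root splits at the 40% prevalence
  infection <- ta$root$branches[[1]]$child
  expect_identical(infection$label, "infection")
  expect_equal(sapply(infection$branches, `[[`, "prob"), c(0.40, 0.60))

  pa <- enumerate_paths(ta)
  expect_true(all(grepl("culture_", pa$path)))

  tn <- build_strategy_tree(baseline, "no_testing", "ceftriaxone_gentamicin")
  pn <- enumerate_paths(tn)
  expect_false(any(grepl("culture_", pn$path)))
  expect_error(build_strategy_tree(baseline, "active_lab", "colistin"),
               class = "labcea_validation_error")
})

test_that("path probabilities are a distribution and concentrate as expected", {
  pa <- enumerate_paths(build_strategy_tree(baseline, "active_lab",
                                            "meropenem_vancomycin"))
  expect_equal(sum(pa$probability), 1, tolerance = 1e-9)

  # with certain infection, culture-positive mass equals the sensitivity
  p1 <- param_set(baseline, "test.prevalence", 1)
  pa1 <- enumerate_paths(build_strategy_tree(p1, "active_lab",
                                             "ceftriaxone_gentamicin"))
  expect_true(all(grepl("/infected/", pa1$path)))
  pos_mass <- sum(pa1$probability[grepl("culture_positive", pa1$path)])
  expect_equal(pos_mass, p1$test$sensitivity, tolerance = 1e-12)
})

test_that("rollback equals path-enumeration expectation on random models", {
  for (seed in 1:40) {
    params <- generate_parameter_set(seed)
    arm <- if (seed %% 2 == 0) "active_lab" else "no_testing"
    regimen <- names(params$regimens)[seed %% 3 + 1]
    tree <- build_strategy_tree(params, arm, regimen)
    paths <- enumerate_paths(tree)
    r <- rollback(tree)
    expect_equal(sum(paths$probability), 1, tolerance = 1e-9)
    expect_equal(r$expected_cost_per_patient,
                 sum(paths$probability * paths$total_cost), tolerance = 1e-9)
    expect_equal(r$expected_deaths_per_patient,
                 sum(paths$probability * paths$death_probability),
                 tolerance = 1e-9)
    expect_equal(r$expected_los_days_per_patient,
                 sum(paths$probability * paths$los_days), tolerance = 1e-9)
  }
})

test_that("a test that never returns positive changes no health outcome", {
  p0 <- param_set(param_set(baseline, "test.sensitivity", 0),
                  "test.false_positive", 0)
  for (regimen in names(p0$regimens)) {
    ra <- rollback(build_strategy_tree(p0, "active_lab", regimen))
    rn <- rollback(build_strategy_tree(p0, "no_testing", regimen))
    expect_equal(ra$expected_deaths_per_patient, rn$expected_deaths_per_patient)
    expect_equal(ra$expected_los_days_per_patient,
                 rn$expected_los_days_per_patient)
    b <- p0$test$bottles_per_patient
    expect_equal(ra$expected_cost_per_patient - rn$expected_cost_per_patient,
                 b * (p0$costs$culture_negative_bottle +
                        p0$costs$maintenance_per_sample),
                 tolerance = 1e-9)
  }
})

test_that("higher culture sensitivity never increases active-arm deaths", {
  deaths <- sapply(seq(0, 1, by = 0.1), function(s) {
    p <- param_set(baseline, "test.sensitivity", s)
    rollback(build_strategy_tree(p, "active_lab",
                                 "ceftriaxone_gentamicin"))$expected_deaths_per_patient
  })
  expect_true(all(diff(deaths) <= 1e-12))
})

test_that("tree JSON export round-trips and re-evaluates identically", {
  tree <- build_strategy_tree(baseline, "active_lab", "ampicillin_gentamicin")
  f <- withr::local_tempfile(fileext = ".json")
  export_tree(tree, f)
  back <- import_tree(f)
  expect_equal(tidy(rollback(back)), tidy(rollback(tree)), tolerance = 1e-12)
  expect_identical(back$fingerprint, tree$fingerprint)
})
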