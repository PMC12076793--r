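# Model parameterisation: construction, validation, load/save, flattening.
#
# A parameter set is a named list with class "labcea_params" holding six
# blocks (test, regimens, transitions, costs, outcomes, daly) plus the
# population label, tree-policy switches, and a `sources` map tagging each
# leaf value as "paper" (printed in the main text) or "placeholder"
# (appendix-only in the source study; shipped here as documented stand-ins).

# canonical keys ---------------------------------------------------------------

.states  <- c("infected_covered", "infected_uncovered", "uninfected")
.changes <- c("improve", "unchanged", "deteriorate")
.switches <- c("step_up", "step_down", "no_change")
.regimen_names <- c("ceftriaxone_gentamicin", "ampicillin_gentamicin",
                    "meropenem_vancomycin")
.populations <- c("adult", "under4")

# schema: nested template of legal keys (leaf value = TRUE)
.params_schema <- function() {
  dist3 <- function(keys) setNames(rep(list(TRUE), length(keys)), keys)
  regimen <- list(name = TRUE, drug_cost_per_day = TRUE, coverage = TRUE,
                  stepup_drug_cost_per_day = TRUE,
                  stepdown_drug_cost_per_day = TRUE)
  list(
    population = TRUE,
    test = list(prevalence = TRUE, sensitivity = TRUE, false_positive = TRUE,
                bottles_per_patient = TRUE, empiric_days = TRUE),
    regimens = setNames(rep(list(regimen), 3L), .regimen_names),
    transitions = list(
      clinical_change = setNames(rep(list(dist3(.changes)), 3L), .states),
      switch = list(culture_positive = dist3(.switches),
                    clinical_only = dist3(.switches))
    ),
    costs = list(culture_positive_bottle = TRUE, culture_negative_bottle = TRUE,
                 maintenance_per_sample = TRUE, maintenance_unit = TRUE,
                 icu_cost_per_day = TRUE, ward_cost_per_day = TRUE,
                 amr_cost_per_course = TRUE, annual_fixed_lab_cost = TRUE,
                 annual_samples = TRUE),
    outcomes = list(
      mortality = setNames(rep(list(dist3(.changes)), 3L), .states),
      los_days = setNames(rep(list(dist3(.changes)), 3L), .states)
    ),
    daly = list(years_lost_per_death = TRUE, disability_weight = TRUE,
                days_per_year = TRUE, cohort_size = TRUE, wtp_per_daly = TRUE),
    policy = list(definitive_days = TRUE, fp_branch_policy = TRUE,
                  coverage_stepup_rule = TRUE, blind_stepup_covers = TRUE),
    sources = NULL  # free-form map of dotted path -> paper/placeholder
  )
}

#' Construct a validated model parameter set
#'
#' Assembles the six parameter blocks of the decision model into a
#' `labcea_params` object and validates every invariant (probabilities in
#' \[0, 1\], distributions summing to one, non-negative costs). Most users
#' will start from [baseline_parameters()] or [generate_parameter_set()]
#' instead of calling this directly.
#'
#' @param population `"adult"` or `"under4"`; selects the DALY constants the
#'   set is intended for (years of life lost per death and disability weight).
#' @param test,regimens,transitions,costs,outcomes,daly,policy Named lists;
#'   see the bundled baseline configuration
#'   (`system.file("extdata", "baseline_adult.yaml", package = "labcea")`)
#'   for the full schema.
#' @param sources Optional named character vector mapping dotted parameter
#'   paths to `"paper"` or `"placeholder"`, recording which values are
#'   printed study inputs and which are documented stand-ins.
#' @return A `labcea_params` object (a validated named list).
#' @export
parameter_set <- function(population, test, regimens, transitions, costs,
                          outcomes, daly, policy, sources = character()) {
  params <- structure(
    list(population = population, test = test, regimens = regimens,
         transitions = transitions, costs = costs, outcomes = outcomes,
         daly = daly, policy = policy, sources = sources),
    class = "labcea_params")
  assert_valid_parameters(params)
  params
}

#' @export
print.labcea_params <- function(x, ...) {
  cat("<labcea_params>  population:", x$population, "\n")
  cat("  prevalence", x$test$prevalence,
      "| sensitivity", x$test$sensitivity,
      "| false positive", x$test$false_positive, "\n")
  cov <- map_dbl(x$regimens, "coverage")
  cat("  regimens:", paste0(names(x$regimens), " (coverage ",
                            format(cov, digits = 3), ")", collapse = ", "), "\n")
  cat("  cohort", x$daly$cohort_size, "patients | WTP $",
      x$daly$wtp_per_daly, "/DALY\n", sep = "")
  invisible(x)
}

# validation -------------------------------------------------------------------

.prob_tol <- 1e-9

# checks return NULL or c(field, rule) pairs; violations become one tibble
# at the end (keeps repeated validation cheap inside the PSA loop)
.check <- function(ok, field, rule) {
  if (isTRUE(ok)) NULL else c(field, rule)
}

.check_dist <- function(p, keys, field) {
  if (!all(keys %in% names(p))) {
    return(c(field, paste0("must have components ",
                           paste(keys, collapse = ", "))))
  }
  p <- unlist(p[keys])
  if (any(!is.finite(p)) || any(p < 0)) {
    c(field, "components must be finite and nonnegative")
  } else if (abs(sum(p) - 1) > .prob_tol) {
    c(field, sprintf("must sum to 1 (got %.10f)", sum(p)))
  } else {
    NULL
  }
}

.check_prob <- function(x, field) {
  .check(is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1,
         field, "must be a probability in [0, 1]")
}

.check_nonneg <- function(x, field) {
  .check(is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0,
         field, "must be a nonnegative number")
}

.check_pos <- function(x, field) {
  .check(is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0,
         field, "must be a positive number")
}

#' List every invariant violation in a parameter set
#'
#' Checks all declared invariants: probabilities lie in \[0, 1\], every
#' transition distribution sums to one within 1e-9, costs are nonnegative,
#' exactly the three study regimens are present, the bottle count is 2 or 4,
#' and — when both the annual fixed laboratory cost and the annual sample
#' count are given — the per-sample maintenance cost is consistent with
#' their quotient to within one cent.
#'
#' @param params A `labcea_params` object (or a bare list with the same shape).
#' @return A tibble with columns `field` and `rule`, one row per violation;
#'   zero rows when every invariant holds. Violations are returned, never
#'   raised.
#' @export
validate_parameters <- function(params) {
  v <- list()
  v <- c(v, list(.check(is.character(params$population) &&
                          params$population %in% .populations,
                        "population", "must be 'adult' or 'under4'")))

  tst <- params$test
  v <- c(v, list(.check_prob(tst$prevalence, "test.prevalence"),
                 .check_prob(tst$sensitivity, "test.sensitivity"),
                 .check_prob(tst$false_positive, "test.false_positive"),
                 .check(is.numeric(tst$bottles_per_patient) &&
                          tst$bottles_per_patient %in% c(2, 4),
                        "test.bottles_per_patient", "must be 2 or 4"),
                 .check_pos(tst$empiric_days, "test.empiric_days")))

  v <- c(v, list(.check(identical(sort(names(params$regimens)),
                                  sort(.regimen_names)),
                        "regimens", "must contain exactly the three study regimens")))
  for (rn in intersect(names(params$regimens), .regimen_names)) {
    r <- params$regimens[[rn]]
    pre <- paste0("regimens.", rn, ".")
    v <- c(v, list(.check_prob(r$coverage, paste0(pre, "coverage")),
                   .check_nonneg(r$drug_cost_per_day, paste0(pre, "drug_cost_per_day")),
                   .check_nonneg(r$stepup_drug_cost_per_day,
                                 paste0(pre, "stepup_drug_cost_per_day")),
                   .check_nonneg(r$stepdown_drug_cost_per_day,
                                 paste0(pre, "stepdown_drug_cost_per_day"))))
  }

  for (s in .states) {
    v <- c(v, list(.check_dist(params$transitions$clinical_change[[s]], .changes,
                               paste0("transitions.clinical_change.", s))))
  }
  for (ctx in c("culture_positive", "clinical_only")) {
    v <- c(v, list(.check_dist(params$transitions$switch[[ctx]], .switches,
                               paste0("transitions.switch.", ctx))))
  }

  cs <- params$costs
  for (f in c("culture_positive_bottle", "culture_negative_bottle",
              "maintenance_per_sample", "icu_cost_per_day", "ward_cost_per_day",
              "amr_cost_per_course", "annual_fixed_lab_cost")) {
    v <- c(v, list(.check_nonneg(cs[[f]], paste0("costs.", f))))
  }
  v <- c(v, list(.check(is.numeric(cs$annual_samples) && cs$annual_samples > 0,
                        "costs.annual_samples", "must be a positive count"),
                 .check(cs$maintenance_unit %in% c("bottle", "set"),
                        "costs.maintenance_unit", "must be 'bottle' or 'set'")))
  if (is.numeric(cs$annual_fixed_lab_cost) && is.numeric(cs$annual_samples) &&
      cs$annual_samples > 0 && is.numeric(cs$maintenance_per_sample)) {
    quo <- cs$annual_fixed_lab_cost / cs$annual_samples
    v <- c(v, list(.check(abs(cs$maintenance_per_sample - quo) <= 0.01 + 1e-9,
                          "costs.maintenance_per_sample",
                          sprintf("inconsistent with annual_fixed_lab_cost/annual_samples = %.4f (cent tolerance)", quo))))
  }

  for (s in .states) {
    for (ch in .changes) {
      v <- c(v, list(
        .check_prob(params$outcomes$mortality[[s]][[ch]],
                    paste0("outcomes.mortality.", s, ".", ch)),
        .check_nonneg(params$outcomes$los_days[[s]][[ch]],
                      paste0("outcomes.los_days.", s, ".", ch))))
    }
  }

  d <- params$daly
  v <- c(v, list(.check_pos(d$years_lost_per_death, "daly.years_lost_per_death"),
                 .check_prob(d$disability_weight, "daly.disability_weight"),
                 .check_pos(d$days_per_year, "daly.days_per_year"),
                 .check_pos(d$cohort_size, "daly.cohort_size"),
                 .check_nonneg(d$wtp_per_daly, "daly.wtp_per_daly")))

  v <- c(v, list(.check_pos(params$policy$definitive_days, "policy.definitive_days")))

  v <- v[!vapply(v, is.null, logical(1))]
  if (length(v) == 0) {
    tibble(field = character(), rule = character())
  } else {
    tibble(field = vapply(v, `[`, character(1), 1L),
           rule = vapply(v, `[`, character(1), 2L))
  }
}

#' Stop with a validation error if a parameter set is invalid
#'
#' @inheritParams validate_parameters
#' @return `params`, invisibly, when valid.
#' @export
assert_valid_parameters <- function(params) {
  v <- validate_parameters(params)
  if (nrow(v) > 0) {
    abort_validation(
      c("Invalid parameter set:",
        setNames(paste0(v$field, ": ", v$rule), rep("x", nrow(v)))),
      violations = v)
  }
  invisible(params)
}

# load / save ------------------------------------------------------------------

.unknown_keys <- function(x, schema, prefix = "") {
  bad <- character()
  for (k in names(x)) {
    path <- paste0(prefix, k)
    if (!k %in% names(schema)) {
      bad <- c(bad, path)
    } else if (is.list(schema[[k]]) && is.list(x[[k]])) {
      bad <- c(bad, .unknown_keys(x[[k]], schema[[k]], paste0(path, ".")))
    }
  }
  bad
}

#' Load a model configuration file
#'
#' Reads a JSON or YAML configuration (selected by file extension), rejects
#' unknown keys, and validates every invariant before returning.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` configuration file.
#' @return A validated `labcea_params` object.
#' @seealso [save_config()], [baseline_parameters()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_io(paste0("config file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
           json = jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE,
                                      simplifyMatrix = FALSE),
           yaml = ,
           yml = yaml::read_yaml(path),
           abort_format(paste0("unsupported config extension: .", ext))),
    error = function(e) {
      if (inherits(e, "labcea_format_error")) rlang::cnd_signal(e)
      abort_format(c(paste0("could not parse ", path),
                     i = conditionMessage(e)))
    })
  if (!is.list(raw)) abort_format("config must be a mapping at top level")
  schema <- .params_schema()
  bad <- .unknown_keys(raw[setdiff(names(raw), "sources")],
                       schema[setdiff(names(schema), "sources")])
  if (length(bad)) {
    abort_format(c("unknown configuration keys:",
                   setNames(bad, rep("x", length(bad)))))
  }
  sources <- unlist(raw$sources %||% list())
  if (length(sources) && !all(sources %in% c("paper", "placeholder"))) {
    abort_format("sources tags must be 'paper' or 'placeholder'")
  }
  parameter_set(population = raw$population, test = raw$test,
                regimens = raw$regimens, transitions = raw$transitions,
                costs = raw$costs, outcomes = raw$outcomes, daly = raw$daly,
                policy = raw$policy, sources = sources)
}

#' Save a model configuration file
#'
#' Writes a `labcea_params` object to JSON (full double precision; the
#' save–load round trip is lossless) or YAML (human-oriented; values are
#' written with 15 significant digits).
#'
#' @param params A validated `labcea_params` object.
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  assert_valid_parameters(params)
  x <- unclass(params)
  x$sources <- as.list(x$sources)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         # I(17) significant digits: doubles survive the round trip bitwise
         json = jsonlite::write_json(x, path, auto_unbox = TRUE,
                                     digits = I(17), pretty = TRUE),
         yaml = ,
         yml = yaml::write_yaml(x, path, precision = 15L),
         abort_format(paste0("unsupported config extension: .", ext)))
  invisible(path)
}

#' Baseline model configuration
#'
#' Loads the bundled baseline parameter set. Values printed in the source
#' study (prevalence 0.40, culture sensitivity 0.80, false-positive rate
#' 0.05, drug costs $1.76/$3.04/$35.16 per day, bottle costs $31.90/$5.80,
#' maintenance $34.53 per sample, DALY constants) are tagged
#' `source: paper`; appendix-only inputs (transition distributions,
#' per-trajectory mortality and length of stay, ICU/ward daily costs,
#' regimen coverages, AMR cost per course) ship as documented placeholders
#' tagged `source: placeholder`.
#'
#' @param population `"adult"` (default) or `"under4"`; selects the DALY
#'   constants (11 years lost per death and disability weight 0.133 for
#'   adults aged 55-59; 66 years and 0.402 for children under four).
#' @return A validated `labcea_params` object.
#' @export
baseline_parameters <- function(population = c("adult", "under4")) {
  population <- arg_match(population)
  path <- system.file("extdata", paste0("baseline_", population, ".yaml"),
                      package = "labcea", mustWork = TRUE)
  load_config(path)
}

# derived quantities -----------------------------------------------------------

#' Per-sample maintenance cost of the laboratory service
#'
#' Divides the annual fixed cost of maintaining the microbiology laboratory
#' by the number of samples processed per year, rounding half-up at the
#' cent (so `maintenance_cost_per_sample(95176, 3813)` is 24.96 and
#' `maintenance_cost_per_sample(131697, 1200)` is 109.75).
#'
#' @param annual_cost Annual fixed laboratory cost, USD.
#' @param annual_samples Samples processed per year; must be positive.
#' @return Cost per sample in USD, rounded to cents.
#' @export
maintenance_cost_per_sample <- function(annual_cost, annual_samples) {
  if (!is.numeric(annual_cost) || any(annual_cost < 0)) {
    abort_validation("annual_cost must be nonnegative")
  }
  if (!is.numeric(annual_samples) || any(annual_samples <= 0)) {
    abort_validation("annual_samples must be positive")
  }
  # round-half-up at the cent (base round() is half-to-even); the epsilon
  # absorbs binary representation error just below the half-cent boundary
  floor(annual_cost / annual_samples * 100 + 0.5 + 1e-9) / 100
}

# flattening -------------------------------------------------------------------

.flatten_params <- function(x, prefix = "") {
  out <- list()
  for (k in names(x)) {
    path <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    val <- x[[k]]
    if (is.list(val)) {
      out <- c(out, list(.flatten_params(val, path)))
    } else {
      out <- c(out, list(tibble(parameter = path,
                                value = as.character(val))))
    }
  }
  bind_rows(out)
}

#' Flatten a parameter set to one row per parameter
#'
#' @inheritParams validate_parameters
#' @return A tibble with columns `parameter` (dotted path), `value`, and
#'   `source` (`"paper"`, `"placeholder"`, or `NA` for structural fields).
#' @export
param_table <- function(params) {
  tab <- .flatten_params(unclass(params)[setdiff(names(params), "sources")])
  src <- params$sources
  tab$source <- unname(src[tab$parameter])
  tab
}

#' Write the flattened parameter table to CSV
#'
#' @inheritParams validate_parameters
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_param_table <- function(params, path) {
  write.csv(param_table(params), path, row.names = FALSE, na = "")
  invisible(path)
}

# path get/set used by DSA, PSA, and scenario construction ---------------------

#' Read or replace one parameter by its dotted path
#'
#' Dotted paths address leaves (or sub-lists) of a parameter set, e.g.
#' `"test.prevalence"` or `"transitions.clinical_change.uninfected"`.
#' `param_set()` returns a modified copy and does not revalidate; call
#' [validate_parameters()] (or any evaluation function, which validates on
#' entry) afterwards.
#'
#' @param params A `labcea_params` object.
#' @param path Dotted parameter path.
#' @param value Replacement value.
#' @return `param_get()`: the value at `path` (`NULL` if absent);
#'   `param_set()`: the modified parameter set.
#' @export
param_get <- function(params, path) {
  purrr::pluck(params, !!!strsplit(path, ".", fixed = TRUE)[[1]])
}

#' @rdname param_get
#' @export
param_set <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  purrr::pluck(params, !!!keys) <- value
  params
}
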