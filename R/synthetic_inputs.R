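# Seeded synthetic inputs: complete valid parameter sets emulating the
# study's elicited inputs, and antibiogram tables with controlled regimen
# coverage. Printed study values are pinned; appendix-style values are
# drawn from the documented plausible ranges in
# inst/extdata/placeholder_ranges.yaml, enforcing only the orderings the
# study states (broad-spectrum coverage highest, ICU dearer than ward,
# uncovered infection worse than covered, deterioration worse than
# improvement).

#' Encode an elicited probability summary as a beta distribution
#'
#' PERT-style moment matching: the elicited (lower, mode, upper) triple is
#' mapped to mean `(lower + 4 mode + upper) / 6`, and the confidence weight
#' acts as an effective sample size, giving `shape1 = mean x weight`,
#' `shape2 = (1 - mean) x weight`. Degenerate bounds (`lower == upper`)
#' return a point mass.
#'
#' @param mode Most plausible value, in \[lower, upper\].
#' @param lower,upper Plausible bounds within \[0, 1\].
#' @param weight Confidence weight (effective sample size), positive.
#' @return A list with `shape1`, `shape2`, `mean`, and `point_mass`
#'   (logical; when `TRUE`, `value` holds the mass point instead of shapes).
#' @export
elicitation_to_beta <- function(mode, lower, upper, weight = 30) {
  if (lower > mode || mode > upper || lower < 0 || upper > 1) {
    abort_validation("need 0 <= lower <= mode <= upper <= 1")
  }
  if (lower == upper) {
    return(list(point_mass = TRUE, value = mode, mean = mode,
                shape1 = NA_real_, shape2 = NA_real_))
  }
  if (weight <= 0) abort_validation("weight must be positive")
  m <- (lower + 4 * mode + upper) / 6
  list(point_mass = FALSE, value = NA_real_, mean = m,
       shape1 = m * weight, shape2 = (1 - m) * weight)
}

.placeholder_ranges <- function() {
  yaml::read_yaml(system.file("extdata", "placeholder_ranges.yaml",
                              package = "labcea", mustWork = TRUE))
}

.runif_range <- function(ranges, key) {
  r <- ranges[[key]]$range
  stats::runif(1, r[[1]], r[[2]])
}

#' Generate a complete synthetic parameter set
#'
#' Produces a validated `labcea_params` with every printed study value
#' pinned (prevalence 0.40, sensitivity 0.80, false-positive 0.05, drug
#' costs 1.76/3.04/35.16 USD/day, bottle costs 31.90/5.80, maintenance
#' 34.53, population-specific DALY constants) and every appendix-style
#' value drawn from the documented plausible ranges, subject to the stated
#' qualitative orderings. Identical seeds give identical sets.
#'
#' @param seed Integer seed.
#' @param population `"adult"` or `"under4"`.
#' @param overrides Optional named list of dotted-path overrides applied
#'   after generation; an override violating invariants raises a
#'   validation error.
#' @return A validated `labcea_params` object.
#' @export
generate_parameter_set <- function(seed, population = c("adult", "under4"),
                                   overrides = NULL) {
  population <- arg_match(population)
  rng <- .placeholder_ranges()
  set.seed(as.integer(seed))
  u <- function(key) .runif_range(rng, key)

  cov_cef <- u("coverage_narrow")
  cov_amp <- u("coverage_narrow")
  lo_broad <- max(rng$coverage_broad$range[[1]], max(cov_cef, cov_amp) + 0.05)
  cov_mero <- stats::runif(1, lo_broad, rng$coverage_broad$range[[2]])

  mk_regimen <- function(name, day_cost, cov) {
    list(name = name, drug_cost_per_day = day_cost, coverage = cov,
         stepup_drug_cost_per_day = u("stepup_drug_cost_per_day"),
         stepdown_drug_cost_per_day = u("stepdown_drug_cost_per_day"))
  }
  regimens <- list(
    ceftriaxone_gentamicin = mk_regimen("ceftriaxone_gentamicin", 1.76, cov_cef),
    ampicillin_gentamicin = mk_regimen("ampicillin_gentamicin", 3.04, cov_amp),
    meropenem_vancomycin = mk_regimen("meropenem_vancomycin", 35.16, cov_mero))

  dist3 <- function(improve, deteriorate) {
    list(improve = improve, unchanged = 1 - improve - deteriorate,
         deteriorate = deteriorate)
  }
  cc_cov <- dist3(u("prob_improve_covered"), u("prob_deteriorate_covered"))
  det_u <- u("prob_deteriorate_uncovered")
  cc_unc <- dist3(stats::runif(1, 0.10, min(0.30, 1 - det_u - 0.05)), det_u)
  cc_non <- dist3(u("prob_improve_uninfected"), u("prob_deteriorate_uninfected"))

  sw_up <- u("switch_stepup_clinical")
  sw_down <- u("switch_stepdown_clinical")
  clin_only <- list(step_up = sw_up, step_down = sw_down,
                    no_change = 1 - sw_up - sw_down)
  pos_up <- stats::runif(1, 0.3, 0.6)
  pos_down <- u("switch_stepdown_weight_positive") * (1 - pos_up)
  culture_pos <- list(step_up = pos_up, step_down = pos_down,
                      no_change = 1 - pos_up - pos_down)

  m_imp_c <- u("mortality_improve_covered")
  m_det_c <- u("mortality_deteriorate_covered")
  m_unc_c <- m_imp_c + stats::runif(1, 0.3, 0.6) * (m_det_c - m_imp_c)
  m_det_u <- u("mortality_deteriorate_uncovered")
  m_imp_u <- min(m_imp_c * stats::runif(1, 1.5, 3), 0.2)
  m_unc_u <- min(m_unc_c * stats::runif(1, 1.5, 2.5), 0.4)
  sc <- u("mortality_uninfected_scale")
  mortality <- list(
    infected_covered = list(improve = m_imp_c, unchanged = m_unc_c,
                            deteriorate = m_det_c),
    infected_uncovered = list(improve = m_imp_u, unchanged = m_unc_u,
                              deteriorate = m_det_u),
    uninfected = list(improve = m_imp_c * sc, unchanged = m_unc_c * sc,
                      deteriorate = m_det_c * sc))

  los_c <- list(improve = u("los_improve"), unchanged = u("los_unchanged"),
                deteriorate = u("los_deteriorate"))
  los_u <- list(improve = los_c$improve + stats::runif(1, 1, 4),
                unchanged = los_c$unchanged + stats::runif(1, 1, 4),
                deteriorate = los_c$deteriorate + stats::runif(1, 2, 6))
  shrink <- stats::runif(1, 0.7, 0.95)
  los_n <- lapply(los_c, function(x) x * shrink)

  daly <- if (population == "adult") {
    list(years_lost_per_death = 11, disability_weight = 0.133,
         days_per_year = 365, cohort_size = 1000, wtp_per_daly = 500)
  } else {
    list(years_lost_per_death = 66, disability_weight = 0.402,
         days_per_year = 365, cohort_size = 1000, wtp_per_daly = 500)
  }

  params <- parameter_set(
    population = population,
    test = list(prevalence = 0.40, sensitivity = 0.80, false_positive = 0.05,
                bottles_per_patient = 2, empiric_days = 3),
    regimens = regimens,
    transitions = list(
      clinical_change = list(infected_covered = cc_cov,
                             infected_uncovered = cc_unc,
                             uninfected = cc_non),
      switch = list(culture_positive = culture_pos, clinical_only = clin_only)),
    costs = list(culture_positive_bottle = 31.90,
                 culture_negative_bottle = 5.80,
                 maintenance_per_sample = 34.53, maintenance_unit = "bottle",
                 icu_cost_per_day = u("icu_cost_per_day"),
                 ward_cost_per_day = u("ward_cost_per_day"),
                 amr_cost_per_course = u("amr_cost_per_course"),
                 annual_fixed_lab_cost = 131697, annual_samples = 3813),
    outcomes = list(mortality = mortality,
                    los_days = list(infected_covered = los_c,
                                    infected_uncovered = los_u,
                                    uninfected = los_n)),
    daly = daly,
    policy = list(definitive_days = round(u("definitive_days")),
                  fp_branch_policy = "informed",
                  coverage_stepup_rule = "one_minus_coverage",
                  blind_stepup_covers = TRUE),
    sources = c(test.prevalence = "paper", test.sensitivity = "paper",
                test.false_positive = "paper",
                costs.maintenance_per_sample = "paper"))

  if (!is.null(overrides)) {
    for (p in names(overrides)) params <- param_set(params, p, overrides[[p]])
    assert_valid_parameters(params)
  }
  params
}

# default mapping of regimen name -> component antibiotic columns
.regimen_components <- list(
  ceftriaxone_gentamicin = c("ceftriaxone", "gentamicin"),
  ampicillin_gentamicin = c("ampicillin", "gentamicin"),
  meropenem_vancomycin = c("meropenem", "vancomycin"))

.organism_pool <- c(
  "Escherichia coli", "Klebsiella pneumoniae", "Staphylococcus aureus",
  "Burkholderia pseudomallei", "Salmonella Typhi", "Acinetobacter baumannii",
  "Pseudomonas aeruginosa", "Enterococcus faecalis",
  "Streptococcus pneumoniae", "Enterobacter cloacae")

#' Generate a synthetic antibiogram with controlled regimen coverage
#'
#' Draws per-isolate susceptibilities so that, under the `any_agent` rule,
#' each regimen's expected coverage equals its target exactly; the computed
#' coverage of the returned table therefore matches each target to within
#' binomial sampling error at `n_isolates`. Per-antibiotic susceptibility
#' probabilities are solved from the targets assuming independence across
#' components; antibiotics shared between regimens (gentamicin) are
#' assigned once, and targets that the shared assignment makes unreachable
#' raise a feasibility error. Isolates are grouped into one row per
#' organism and resistance pattern.
#'
#' @param seed Integer seed.
#' @param n_organisms Number of organism labels to draw from (max 10).
#' @param n_isolates Total isolates in the table.
#' @param targets Named numeric vector/list of target coverages in
#'   \[0, 1\], one per regimen (defaults cover all three study regimens).
#' @param components Mapping of regimen name to component antibiotics.
#' @return An antibiogram tibble consumable by [regimen_coverage()]:
#'   `organism`, `isolates`, one `S`/`R` column per antibiotic.
#' @export
generate_antibiogram <- function(seed, n_organisms = 6, n_isolates = 500,
                                 targets = c(ceftriaxone_gentamicin = 0.60,
                                             ampicillin_gentamicin = 0.55,
                                             meropenem_vancomycin = 0.85),
                                 components = .regimen_components[names(targets)]) {
  targets <- unlist(targets)
  if (any(targets < 0 | targets > 1)) {
    abort_validation("targets must be probabilities in [0, 1]")
  }
  if (n_isolates < 1 || n_organisms < 1) {
    abort_validation("n_organisms and n_isolates must be positive")
  }
  # solve per-antibiotic susceptibility probabilities regimen by regimen
  p_abx <- c()
  for (rgn in names(targets)) {
    comp <- components[[rgn]]
    assigned <- intersect(comp, names(p_abx))
    free <- setdiff(comp, names(p_abx))
    q_assigned <- prod(1 - p_abx[assigned])
    resid <- (1 - targets[[rgn]]) / q_assigned
    if (length(free) == 0) {
      if (abs((1 - q_assigned) - targets[[rgn]]) > 1e-9) {
        abort_validation(paste0("joint targets infeasible for ", rgn))
      }
      next
    }
    if (resid > 1 + 1e-12) {
      abort_validation(paste0("joint targets infeasible for ", rgn,
                              ": shared components already imply higher coverage"))
    }
    # shared components take a conservative half-share of the first regimen's
    # coverage so later regimens sharing them remain solvable
    if (length(free) == length(comp) && length(comp) > 1 &&
        any(sapply(names(targets), function(o) {
          o != rgn && length(intersect(components[[o]], comp)) > 0
        }))) {
      shared <- free[sapply(free, function(a) {
        any(sapply(setdiff(names(targets), rgn), function(o) a %in% components[[o]]))
      })]
      for (a in shared) {
        p_abx[a] <- 0.5 * min(targets[sapply(components, function(cc) a %in% cc)])
      }
      assigned <- intersect(comp, names(p_abx))
      free <- setdiff(comp, names(p_abx))
      resid <- (1 - targets[[rgn]]) / prod(1 - p_abx[assigned])
      if (resid > 1 + 1e-12) {
        abort_validation(paste0("joint targets infeasible for ", rgn))
      }
    }
    if (length(free) > 0) {
      p_each <- 1 - pmin(1, resid)^(1 / length(free))
      for (a in free) p_abx[a] <- p_each
    }
  }

  set.seed(as.integer(seed))
  n_organisms <- min(n_organisms, length(.organism_pool))
  orgs <- sample(.organism_pool, n_organisms)
  iso_org <- sample(orgs, n_isolates, replace = TRUE)
  status <- lapply(names(p_abx), function(a) {
    ifelse(stats::runif(n_isolates) < p_abx[[a]], "S", "R")
  })
  df <- as_tibble(setNames(status, names(p_abx))) %>%
    mutate(org = iso_org) %>%
    group_by(across(dplyr::everything())) %>%
    summarise(isolates = n(), .groups = "drop")
  # one row per organism x pattern; unique labels carry a pattern suffix
  df %>%
    group_by(.data$org) %>%
    mutate(organism = if (n() > 1) {
      paste0(.data$org, " [pattern ", dplyr::row_number(), "]")
    } else .data$org) %>%
    ungroup() %>%
    select(all_of(c("organism", "isolates", names(p_abx))))
}
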