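# Two-arm decision tree: construction, exhaustive path enumeration (the
# oracle), and expected-value rollback.
#
# Topology (active arm): decision root (arm selection; empiric drug course and
# first AMR-externality charge) -> chance: true infection (prevalence) ->
# chance: culture result (sensitivity | false-positive; laboratory costs
# charged here) -> chance: antibiotic switch (result-informed when culture is
# positive, clinical-condition-only otherwise) -> [infected, blind switch
# only] chance: does the final regimen cover the organism -> chance: clinical
# change (improve / unchanged / deteriorate; care costs charged here) ->
# terminal (mortality, length of stay). The no-testing arm drops the
# culture-result layer and all laboratory costs.

new_node <- function(kind, label, branches = list(), payload = NULL) {
  structure(list(kind = kind, label = label, branches = branches,
                 payload = payload), class = "labcea_node")
}

branch <- function(prob, label, cost, child) {
  list(prob = prob, label = label, cost = cost, child = child)
}

terminal_node <- function(label, death_probability, los_days) {
  new_node("terminal", label,
           payload = list(death_probability = death_probability,
                          los_days = los_days))
}

# result-informed switch distribution for a culture-positive patient:
# step-up probability is 1 - coverage of the empiric regimen (switch to
# covering therapy); the remaining mass `coverage` is split between
# no_change and step_down in the proportions of the elicited
# culture-positive switch weights.
informed_switch_dist <- function(coverage, elicited) {
  w <- unlist(elicited[c("step_down", "no_change")])
  if (sum(w) <= 0) w <- c(step_down = 0, no_change = 1)
  w <- w / sum(w)
  c(step_up = 1 - coverage,
    step_down = coverage * w[["step_down"]],
    no_change = coverage * w[["no_change"]])
}

# terminal layer: clinical-change chance node for a patient in `state`,
# with care costs (ICU for deterioration, ward otherwise) on its branches
clinical_node <- function(params, state) {
  cc <- params$transitions$clinical_change[[state]]
  brs <- lapply(.changes, function(ch) {
    los <- params$outcomes$los_days[[state]][[ch]]
    daily <- if (ch == "deteriorate") params$costs$icu_cost_per_day
             else params$costs$ward_cost_per_day
    branch(cc[[ch]], ch, daily * los,
           terminal_node(paste(state, ch, sep = ":"),
                         params$outcomes$mortality[[state]][[ch]], los))
  })
  new_node("chance", paste0("clinical[", state, "]"), brs)
}

# resolve an infected patient's state after a switch decision that was NOT
# informed by a culture result: blind step-up is assumed to reach covering
# therapy; otherwise coverage of the empiric regimen decides
blind_state_node <- function(params, regimen, action) {
  cov <- params$regimens[[regimen]]$coverage
  if (action == "step_up" && isTRUE(params$policy$blind_stepup_covers)) {
    return(clinical_node(params, "infected_covered"))
  }
  new_node("chance", paste0("coverage[", action, "]"), list(
    branch(cov, "covered", 0, clinical_node(params, "infected_covered")),
    branch(1 - cov, "uncovered", 0,
           clinical_node(params, "infected_uncovered"))))
}

# drug + AMR cost attached to a switch branch; a switch starts a second
# antibiotic course, so it carries a second AMR-externality charge
switch_cost <- function(params, regimen, action) {
  r <- params$regimens[[regimen]]
  days <- params$policy$definitive_days
  amr <- params$costs$amr_cost_per_course
  switch(action,
         step_up = r$stepup_drug_cost_per_day * days + amr,
         step_down = r$stepdown_drug_cost_per_day * days + amr,
         no_change = r$drug_cost_per_day * days)
}

switch_node <- function(params, regimen, dist, child_fn) {
  brs <- lapply(.switches, function(a) {
    branch(dist[[a]], a, switch_cost(params, regimen, a), child_fn(a))
  })
  new_node("chance", "switch", brs)
}

lab_cost <- function(params, positive) {
  b <- params$test$bottles_per_patient
  bottle <- if (positive) params$costs$culture_positive_bottle
            else params$costs$culture_negative_bottle
  maint_units <- if (identical(params$costs$maintenance_unit, "set")) 1 else b
  b * bottle + maint_units * params$costs$maintenance_per_sample
}

#' Build one arm of the decision tree
#'
#' Constructs the decision tree for a single comparison arm and empiric
#' regimen from a validated parameter set. The active-laboratory arm routes
#' patients through a culture-result layer (charging bottle and maintenance
#' costs) where positive results trigger susceptibility-informed antibiotic
#' switching; the no-testing arm switches on clinical condition alone and
#' incurs no laboratory costs.
#'
#' @param params A validated `labcea_params` object.
#' @param arm `"active_lab"` or `"no_testing"`.
#' @param regimen One of `"ceftriaxone_gentamicin"`, `"ampicillin_gentamicin"`,
#'   `"meropenem_vancomycin"`.
#' @param validate Re-validate `params` and fingerprint them (default). The
#'   PSA loop disables this for draws already validated upstream.
#' @return A `labcea_tree` object with fields `root`, `arm`, `regimen`, and a
#'   parameter fingerprint.
#' @export
build_strategy_tree <- function(params, arm = c("active_lab", "no_testing"),
                                regimen, validate = TRUE) {
  if (validate) assert_valid_parameters(params)
  arm <- arg_match(arm)
  if (!regimen %in% names(params$regimens)) {
    abort_validation(paste0("unknown regimen: ", regimen))
  }
  tst <- params$test
  r <- params$regimens[[regimen]]
  elicited <- params$transitions$switch$culture_positive
  clin_only <- unlist(params$transitions$switch$clinical_only)

  # infected subtree after the infection chance node
  if (arm == "active_lab") {
    pos_dist <- informed_switch_dist(r$coverage, elicited)
    infected_child <- new_node("chance", "culture", list(
      branch(tst$sensitivity, "culture_positive", lab_cost(params, TRUE),
             switch_node(params, regimen, as.list(pos_dist), function(a) {
               # susceptibility-guided therapy covers whatever the action
               clinical_node(params, "infected_covered")
             })),
      branch(1 - tst$sensitivity, "culture_negative", lab_cost(params, FALSE),
             switch_node(params, regimen, as.list(clin_only), function(a) {
               blind_state_node(params, regimen, a)
             }))))
    uninfected_child <- new_node("chance", "culture", list(
      branch(tst$false_positive, "culture_positive", lab_cost(params, TRUE),
             switch_node(params, regimen, as.list(pos_dist), function(a) {
               clinical_node(params, "uninfected")
             })),
      branch(1 - tst$false_positive, "culture_negative", lab_cost(params, FALSE),
             switch_node(params, regimen, as.list(clin_only), function(a) {
               clinical_node(params, "uninfected")
             }))))
  } else {
    infected_child <- switch_node(params, regimen, as.list(clin_only),
                                  function(a) blind_state_node(params, regimen, a))
    uninfected_child <- switch_node(params, regimen, as.list(clin_only),
                                    function(a) clinical_node(params, "uninfected"))
  }

  infection <- new_node("chance", "infection", list(
    branch(tst$prevalence, "infected", 0, infected_child),
    branch(1 - tst$prevalence, "uninfected", 0, uninfected_child)))

  # decision root: the designated arm is the single selected branch; the
  # empiric course (drug-days plus one AMR-externality charge) starts here
  empiric_cost <- r$drug_cost_per_day * tst$empiric_days +
    params$costs$amr_cost_per_course
  root <- new_node("decision", "arm",
                   list(branch(NA_real_, arm, empiric_cost, infection)))

  structure(list(root = root, arm = arm, regimen = regimen,
                 fingerprint = if (validate) .params_fingerprint(params)
                               else NA_character_),
            class = "labcea_tree")
}

.params_fingerprint <- function(params) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  x <- unclass(params)
  x$sources <- as.list(x$sources)
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' @export
print.labcea_tree <- function(x, ...) {
  paths <- enumerate_paths(x)
  cat("<labcea_tree> arm:", x$arm, "| regimen:", x$regimen,
      "|", nrow(paths), "terminal paths\n")
  invisible(x)
}

# path enumeration (oracle) ----------------------------------------------------

#' Enumerate every root-to-terminal path of a strategy tree
#'
#' Exhaustively walks the tree, multiplying probabilities and summing cost
#' increments along each branch. Serves as the independent oracle for
#' [rollback()]: the probability-weighted sums over paths must equal the
#' rolled-back expected values.
#'
#' @param tree A `labcea_tree` from [build_strategy_tree()].
#' @param max_depth Depth guard; exceeding it raises a structural error
#'   (a finite tree this deep indicates a malformed or cyclic structure).
#' @return A tibble with one row per path: `path` (branch labels joined by
#'   `/`), `probability`, `total_cost`, `death_probability`, `los_days`.
#' @export
enumerate_paths <- function(tree, max_depth = 50L) {
  walk_node <- function(node, prob, cost, labels, depth) {
    if (depth > max_depth) {
      rlang::abort("tree deeper than max_depth: cycle suspected",
                   class = "labcea_structure_error")
    }
    if (node$kind == "terminal") {
      return(list(tibble(path = paste(labels, collapse = "/"),
                         probability = prob, total_cost = cost,
                         death_probability = node$payload$death_probability,
                         los_days = node$payload$los_days)))
    }
    out <- list()
    for (b in node$branches) {
      if (node$kind == "chance" && b$prob == 0) next  # unreachable path
      p <- if (node$kind == "decision") prob else prob * b$prob
      out <- c(out, walk_node(b$child, p, cost + b$cost,
                              c(labels, b$label), depth + 1L))
    }
    out
  }
  bind_rows(walk_node(tree$root, 1, 0, character(), 0L))
}

# rollback ---------------------------------------------------------------------

#' Evaluate a strategy tree by expected-value rollback
#'
#' Computes per-patient expected cost, expected deaths, and expected
#' hospital days by bottom-up expectation over chance nodes. Decision nodes
#' select their designated arm branch; no expected-value optimisation is
#' performed (the model compares fixed policies).
#'
#' @param tree A `labcea_tree` from [build_strategy_tree()].
#' @return A `labcea_result` list: `expected_cost_per_patient`,
#'   `expected_deaths_per_patient`, `expected_los_days_per_patient`, plus
#'   the arm and regimen labels.
#' @export
rollback <- function(tree) {
  roll <- function(node) {
    if (node$kind == "terminal") {
      return(c(cost = 0, deaths = node$payload$death_probability,
               los = node$payload$los_days))
    }
    acc <- c(cost = 0, deaths = 0, los = 0)
    for (b in node$branches) {
      v <- roll(b$child)
      w <- if (node$kind == "decision") 1 else b$prob
      acc <- acc + w * c(cost = v[["cost"]] + b$cost,
                         deaths = v[["deaths"]], los = v[["los"]])
    }
    acc
  }
  v <- roll(tree$root)
  structure(list(arm = tree$arm, regimen = tree$regimen,
                 expected_cost_per_patient = v[["cost"]],
                 expected_deaths_per_patient = v[["deaths"]],
                 expected_los_days_per_patient = v[["los"]]),
            class = "labcea_result")
}

#' @export
print.labcea_result <- function(x, ...) {
  cat(sprintf("<labcea_result> %s / %s\n", x$arm, x$regimen))
  cat(sprintf("  E[cost/patient]  $%.2f\n", x$expected_cost_per_patient))
  cat(sprintf("  E[deaths/patient] %.4f\n", x$expected_deaths_per_patient))
  cat(sprintf("  E[LOS/patient]    %.2f days\n", x$expected_los_days_per_patient))
  invisible(x)
}

#' @rdname tidy
#' @exportS3Method generics::tidy
tidy.labcea_result <- function(x, ...) {
  tibble(arm = x$arm, regimen = x$regimen,
         expected_cost_per_patient = x$expected_cost_per_patient,
         expected_deaths_per_patient = x$expected_deaths_per_patient,
         expected_los_days_per_patient = x$expected_los_days_per_patient)
}

# JSON export / import ---------------------------------------------------------

.node_to_list <- function(node) {
  out <- list(kind = node$kind, label = node$label)
  if (node$kind == "terminal") {
    out$payload <- node$payload
  } else {
    out$branches <- lapply(node$branches, function(b) {
      list(prob = b$prob, label = b$label, cost = b$cost,
           child = .node_to_list(b$child))
    })
  }
  out
}

.node_from_list <- function(x) {
  if (x$kind == "terminal") {
    return(terminal_node(x$label, x$payload$death_probability,
                         x$payload$los_days))
  }
  new_node(x$kind, x$label, lapply(x$branches, function(b) {
    branch(if (is.null(b$prob)) NA_real_ else b$prob, b$label, b$cost,
           .node_from_list(b$child))
  }))
}

#' Export a strategy tree to JSON for audit or re-import
#'
#' @param tree A `labcea_tree`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
export_tree <- function(tree, path) {
  jsonlite::write_json(
    list(arm = tree$arm, regimen = tree$regimen,
         fingerprint = tree$fingerprint, root = .node_to_list(tree$root)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Re-import a strategy tree exported with [export_tree()]
#'
#' @param path Path to the exported JSON file.
#' @return A `labcea_tree`.
#' @export
import_tree <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(root = .node_from_list(x$root), arm = x$arm,
                 regimen = x$regimen, fingerprint = x$fingerprint),
            class = "labcea_tree")
}
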