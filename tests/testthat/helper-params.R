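# shared fixtures: all built in code, no stored data

baseline <- baseline_parameters("adult")

# a hand-built two-branch toy tree: one chance node, two costed terminals
toy_tree <- function(p1 = 0.5, cost1 = 10, cost2 = 20, d1 = 0, d2 = 0,
                     los1 = 0, los2 = 0) {
  chance <- labcea:::new_node("chance", "toss", list(
    labcea:::branch(p1, "heads", cost1,
                    labcea:::terminal_node("t1", d1, los1)),
    labcea:::branch(1 - p1, "tails", cost2,
                    labcea:::terminal_node("t2", d2, los2))))
  structure(list(root = chance, arm = "active_lab", regimen = "toy",
                 fingerprint = "toy"), class = "labcea_tree")
}

# brute-force antibiogram coverage: expand to per-isolate rows and tally
coverage_by_enumeration <- function(table, antibiotics, rule) {
  rows <- table[rep(seq_len(nrow(table)), table$isolates), antibiotics,
                drop = FALSE]
  status <- as.matrix(rows)
  known <- rowSums(is.na(status)) == 0
  covered <- if (rule == "any_agent") {
    rowSums(status == "S", na.rm = TRUE) >= 1
  } else {
    rowSums(status == "S", na.rm = TRUE) == length(antibiotics)
  }
  sum(covered & known) / sum(known)
}

# expected laboratory cost per patient (bottles x result-weighted bottle
# price + maintenance), used by closed-form cost-delta checks
expected_lab_cost <- function(params) {
  tst <- params$test
  p_pos <- tst$prevalence * tst$sensitivity +
    (1 - tst$prevalence) * tst$false_positive
  bottle <- p_pos * params$costs$culture_positive_bottle +
    (1 - p_pos) * params$costs$culture_negative_bottle
  tst$bottles_per_patient * (bottle + params$costs$maintenance_per_sample)
}
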