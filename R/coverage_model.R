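# Empiric-regimen coverage from an antibiogram: the isolate-count-weighted
# probability that the regimen is active against the causative organism.

#' Read an antibiogram CSV
#'
#' Expected dialect: UTF-8, comma-separated, header row with `organism`,
#' `isolates`, then one column per antibiotic holding `S`, `R`, `I` or
#' empty/`unknown`. Intermediate (`I`) results are mapped to `R` by default
#' (conservative); empty cells become unknown and are excluded from
#' coverage computations.
#'
#' @param path CSV file path.
#' @param intermediate_as How to treat `I` results: `"R"` (default) or `"S"`.
#' @return A tibble: `organism`, `isolates`, antibiotic columns with values
#'   in `{"S", "R", NA}`.
#' @export
read_antibiogram <- function(path, intermediate_as = c("R", "S")) {
  intermediate_as <- arg_match(intermediate_as)
  if (!file.exists(path)) abort_io(paste0("antibiogram file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (!all(c("organism", "isolates") %in% names(df))) {
    abort_format("antibiogram must have 'organism' and 'isolates' columns")
  }
  abx <- setdiff(names(df), c("organism", "isolates"))
  if (length(abx) == 0) abort_format("antibiogram needs at least one antibiotic column")
  tab <- as_tibble(df) %>%
    mutate(across(all_of(abx), function(x) {
      x <- toupper(trimws(as.character(x)))
      x[x == "I"] <- intermediate_as
      x[!x %in% c("S", "R")] <- NA_character_
      x
    }))
  .assert_antibiogram(tab)
  tab
}

.assert_antibiogram <- function(table) {
  if (nrow(table) == 0) abort_validation("antibiogram table is empty")
  if (anyDuplicated(table$organism)) {
    abort_validation("organism labels must be unique")
  }
  counts <- table$isolates
  if (!is.numeric(counts) || any(counts <= 0) || any(counts != round(counts))) {
    abort_validation("isolate counts must be positive integers")
  }
  invisible(table)
}

#' Probability that a regimen covers the causative organism
#'
#' Computes the isolate-count-weighted fraction of isolates covered by a
#' regimen. Under the default `any_agent` rule an isolate is covered when
#' it is susceptible to at least one regimen component (combination therapy
#' covers if any component is active); under `all_agents` it must be
#' susceptible to every component. Isolates with unknown susceptibility to
#' any regimen component are excluded from numerator and denominator; the
#' excluded count is attached as the `excluded_isolates` attribute.
#'
#' @param table An antibiogram tibble ([read_antibiogram()] or
#'   [generate_antibiogram()]).
#' @param antibiotics Character vector of regimen components; each must be
#'   a column of `table`.
#' @param rule `"any_agent"` (default) or `"all_agents"`.
#' @return Coverage probability in \[0, 1\].
#' @export
regimen_coverage <- function(table, antibiotics, rule = c("any_agent", "all_agents")) {
  rule <- arg_match(rule)
  .assert_antibiogram(table)
  missing_cols <- setdiff(antibiotics, names(table))
  if (length(antibiotics) == 0 || length(missing_cols)) {
    abort_validation(paste0("antibiotic columns missing from table: ",
                            paste(missing_cols, collapse = ", ")))
  }
  status <- as.matrix(table[, antibiotics, drop = FALSE])
  known <- rowSums(is.na(status)) == 0
  if (!any(known)) abort_validation("no isolates with fully known susceptibility")
  covered <- if (rule == "any_agent") {
    rowSums(status == "S", na.rm = TRUE) >= 1
  } else {
    rowSums(status == "S", na.rm = TRUE) == length(antibiotics)
  }
  n <- table$isolates
  out <- sum(n[known & covered]) / sum(n[known])
  attr(out, "excluded_isolates") <- sum(n[!known])
  out
}
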