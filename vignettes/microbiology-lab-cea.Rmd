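---
title: "Methods: decision-tree cost-effectiveness of an active microbiology laboratory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree cost-effectiveness of an active microbiology laboratory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labcea)
```

## The decision problem

A hospitalised patient is suspected of having a bloodstream infection. With
an **active microbiology laboratory**, blood cultures are drawn, empiric
antibiotics are started (3 days before reassessment), and a positive culture
with susceptibility results can redirect therapy; without testing, therapy
changes on clinical grounds alone. Testing costs money — bottles, consumables
and the fixed cost of keeping a laboratory running — but timely targeted
therapy is expected to reduce ICU admissions, deaths, and length of stay.
The package quantifies this trade-off for a cohort of 1000 patients, for
three empiric regimens used in the study setting (Timor-Leste's national
referral hospital): ceftriaxone + gentamicin, ampicillin + gentamicin, and
meropenem + vancomycin. All money is 2022 USD, undiscounted; no time
discounting is applied to health outcomes either, since the horizon is a
single admission.

## Tree topology

Both arms are evaluated as rooted decision trees (`build_strategy_tree()`),
with expectations computed by bottom-up rollback and independently cross-checked
by exhaustive path enumeration (the two must agree to 1e-9 on every model —
this is a standing property test, not just a development aid). Decision
nodes are resolved by arm selection, never by expected-value optimisation:
the comparison is between two fixed policies.

Active arm, in order:

1. **True infection** (chance, prevalence 0.40): an imperfectly observed
   latent state.
2. **Culture result** (chance): positive with probability 0.80 (sensitivity)
   if infected, 0.05 (false-positive rate) otherwise. Laboratory costs
   attach here: bottles × bottle price (positive $31.90 / negative $5.80)
   plus maintenance ($34.53 per sample at baseline).
3. **Antibiotic switch** (chance). After a *positive* culture the switch is
   result-informed: the step-up probability is `1 − coverage` of the empiric
   regimen (the laboratory reveals an organism the regimen misses), and the
   remaining mass `coverage` is split between *no change* and *step down* in
   the proportions of the elicited culture-positive switch weights. After a
   *negative* culture the elicited clinical-condition-only distribution is
   used — identical to the no-testing arm. Definitive drug costs (per-day
   price × `policy.definitive_days`) attach to each switch branch, and a
   switch starts a second antibiotic course, carrying a second
   antimicrobial-resistance externality charge (`amr_cost_per_course`; the
   first is charged with the empiric course at the root).
4. **Coverage resolution** (chance; infected patients whose switch was not
   culture-informed): the final regimen covers the organism with probability
   `coverage`; blind step-up is assumed to reach covering broad-spectrum
   therapy (`policy.blind_stepup_covers`). Culture-positive patients end
   covered whatever the switch action, because the action is
   susceptibility-guided.
5. **Clinical course** (chance: improve / unchanged / deteriorate) and a
   terminal with trajectory mortality and length of stay. Deterioration is
   costed at the ICU daily rate × LOS; improvement and no change at the ward
   rate, following the study's costing convention.

The no-testing arm drops layer 2 (and its costs) and always uses the
clinical-condition-only switch distribution.

**Context keying.** Clinical-course, mortality and LOS inputs are keyed by
three patient states — `infected_covered`, `infected_uncovered`,
`uninfected` — rather than by every arm × culture-result combination. Given
the state, the treatment outcome should not depend on which arm produced it;
the arm and culture result act through the switching layer that determines
the state. This keeps the elicited-input surface small and auditable. The
builder is table-driven from the configuration, so a finer keying can be
expressed by editing the transition block without touching the engine.

**False positives.** The study does not describe the uninfected,
culture-positive branch. Here (`policy.fp_branch_policy = "informed"`) such
patients receive result-informed switching — typically costly escalation —
but keep the uninfected clinical-course distribution: a false positive
wastes money, it does not create disease.

## Parameters

Every input lives in one configuration file (YAML or JSON; schema in
`inst/schema/parameterset.schema.json`), loadable with `load_config()` and
validated by `validate_parameters()`: probabilities in [0, 1], every
distribution summing to 1 within 1e-9, nonnegative costs, bottle count in
{2, 4}. Each leaf is tagged `paper` (printed in the study's main text) or
`placeholder` (appendix-only; stand-ins shipped here). Two deliberate
conventions:

* `maintenance_per_sample` is 34.53 at baseline *verbatim*, although
  131,697 / 3,813 rounds to 34.54 at the cent; the printed value is treated
  as authoritative for the baseline, while `maintenance_cost_per_sample()`
  itself rounds half-up at the cent (which reproduces the other printed
  quotients, 24.96 and 109.75). The validator accepts the pair within one
  cent.
* Whether maintenance is charged per bottle or per two-bottle set is
  ambiguous in the source; it is an explicit switch
  (`costs.maintenance_unit`, default `bottle`), not a silent assumption.

Placeholder values were chosen once, from the ranges documented in
`inst/extdata/placeholder_ranges.yaml`, to be clinically plausible and
consistent with the qualitative structure the study reports: the
broad-spectrum regimen has the highest coverage; ICU care ($380/day at
baseline) costs far more than ward care ($48/day); uncovered infection
deteriorates more often (50% vs 10%) and kills more often than covered
infection; deterioration is worse than improvement. DALY constants:
`years_lost_per_death` 11 (adults 55–59; 66 under age four; 20 in a
sensitivity variant), disability weight 0.133 (0.402 under four),
`days_per_year` 365 (no convention was stated; 365.25 would change YLD by
0.07%), cohort 1000, willingness to pay $500 per DALY averted. The loss
function is a per-death constant, not a life-table integral, matching the
single figures the study quotes; no age weighting or discounting is applied
to DALYs, consistent with current burden-of-disease practice.

## Cost-effectiveness metrics

`compare_arms()` scales per-patient expectations to the cohort exactly once
and reports incremental cost, DALYs averted, deaths averted, the ICER and
net monetary benefit. The ICER is never reported as a signed ratio for
dominant or dominated pairs — a negative ratio is uninterpretable — and a
zero denominator yields an explicit `undefined` flag rather than infinite
arithmetic. The south-west quadrant (cheaper, less effective) is labelled as
such because there a *smaller* ratio favours the comparator.

## Probabilistic sensitivity analysis

`default_uncertainty()` assigns Dirichlet distributions to the multinomial
transition nodes, beta distributions to binary probabilities (prevalence,
sensitivity, false-positive rate, coverages, trajectory mortalities), and
lognormal distributions to the ICU and ward daily costs (avoiding negative
draws). Hyperparameters are moment-matched around the configured values:
Dirichlet concentration = mean vector × ESS; beta `(m·ESS, (1−m)·ESS)`;
lognormal `sdlog = sqrt(log(1 + cv²))`, `meanlog = log(m) − sdlog²/2` so the
*arithmetic* mean is preserved. The study states neither the elicitation
ESS nor the cost spread, so the defaults — ESS 30 (moderate panel
confidence) and cv 0.3 — are package choices, overridable per parameter;
published interquartile ranges consequently cannot be recovered exactly and
are not targets. Length-of-stay values stay fixed by default; their cost
effect is already captured through the daily-rate distributions.

`run_psa()` (5000 iterations in the study design) draws all parameters
independently (no correlation structure was described), rebuilds both trees
per draw, and resamples any draw violating an invariant up to 100 times
before aborting with diagnostics — resampling, not clipping, avoids silent
bias at the boundaries; with the default distributions violations are
essentially impossible, the guard exists for user-supplied specs. All
randomness flows from one integer seed; identical seed and configuration
give bitwise-identical output, and summaries (means, quartiles) are
order-independent by construction. Quantiles use linear interpolation
between order statistics (R type 7), pinned for reproducibility; the IQR is
the 25th–75th percentile pair. `ce_plane()` classifies draws into
cost-effectiveness-plane quadrants (lower-right = dominant) and `ceac()`
reports, for each willingness-to-pay value, the fraction of draws with
nonnegative net monetary benefit; at WTP 0 this is the cost-saving
probability.

## Deterministic sensitivity analysis and thresholds

`one_way()` re-evaluates the model over a value grid for a single dotted
parameter path with everything else at baseline, aborting (not clamping) on
invariant violations; `tornado()` orders parameters by absolute swing in
incremental cost. The study's low/high values for prevalence, ICU risk and
mortalities are appendix-only, so scenario grids are caller-supplied.

`breakeven()` searches for the point where a criterion — cost-saving, or
cost-effective at the configured willingness to pay — flips. For
`maintenance_per_sample` it bisects to $0.01. For `annual_samples` the
per-sample maintenance cost is recomputed as
`annual_fixed_lab_cost / annual_samples` at every step (the fixed annual
cost of $131,697 spread over volume) and the result is the smallest integer
volume satisfying the criterion, since sample counts are integers. Both
require the criterion to differ at the bounds and report bracketing evidence
(criterion values just below and above the threshold); an unbracketed search
raises a classed error with endpoint diagnostics. Bisection agrees with an
exhaustive grid scan at the tolerance — a tested property, and one of the
acceptance checks.

## Coverage from antibiograms

`regimen_coverage()` computes the isolate-count-weighted probability that a
regimen is active against the causative organism from an S/R table. The
default rule is `any_agent` — combination therapy covers if any component is
active — with `all_agents` available, since the study's exact calculation is
appendix-only; `any_agent` coverage always dominates `all_agents`.
Intermediate results are mapped to resistant by the reader (conservative,
overridable), and isolates with unknown status for any regimen component are
excluded from numerator and denominator with the excluded count reported.
No MIC breakpoint interpretation is attempted: input is already categorised.

## Synthetic inputs

`generate_parameter_set()` emulates the *form* of the study's inputs — the
printed values pinned exactly, the appendix-only values drawn from the
documented plausible ranges — enforcing only the orderings the study states
and leaving everything else free, to avoid inventing unstated structure.
`elicitation_to_beta()` encodes an elicited (lower, mode, upper, confidence)
summary as a beta distribution via PERT moment matching, the same form an
elicitation exercise would produce. `generate_antibiogram()` solves
per-antibiotic susceptibility probabilities so each regimen's expected
any-agent coverage equals its target exactly (shared components such as
gentamicin are assigned a conservative half-share first; unreachable joint
targets raise a feasibility error), making observed coverage binomial around
the target.

What the generator does *not* emulate: correlations between elicited
quantities, organism-specific outcome differences, secular trends in
resistance, or any reverse-engineering of the appendix values from published
totals (that system is underdetermined). Tests passing on synthetic inputs
therefore demonstrate the *machinery* — validity, invariants, limits,
reproducibility — on models with realistic structure, not agreement with the
study's absolute cost and DALY totals, which depend on the appendix-only
parameters.

## Numerical choices and problem sizes

Probability-sum and oracle-equivalence tolerances are 1e-9; monetary
rounding is half-up at the cent with a 1e-9 epsilon absorbing binary
representation error at the half-cent boundary; JSON configuration output
uses 17 significant digits so a save–load round trip is bitwise lossless
(YAML uses 15, for human reading). The test suite exercises the
rollback/enumeration equivalence on 40 random models (200 in the acceptance
script), distribution moment checks at n = 50,000 draws, PSA runs of 10–60
iterations for reproducibility and shrink-to-point-mass checks, and
grid-scan confirmation of thresholds over windows of several hundred
volumes; the acceptance script additionally runs the full 5000-iteration
probabilistic analysis. These sizes were chosen to make the checks sharp
(3-standard-error bounds) while keeping a complete run in the low minutes on
one CPU.

## Known limitations

* Absolute cost/DALY totals inherit the placeholder inputs; only structure,
  printed arithmetic, and qualitative findings are reproducible from the
  main text.
* The tree is a single-admission model: no Markov extension, no
  microsimulation, no long-term resistance dynamics, no benefit assigned to
  de-escalation beyond its drug-cost saving (a conservative assumption).
* Culture-negative patients in the active arm are treated identically to
  no-testing patients except for laboratory costs; any result-waiting delay
  penalty would need an explicit extra parameter.
* Mortality and stay are assumed equal across regimens given the patient
  state; regimen differences act through coverage and switching only.
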