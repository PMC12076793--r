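# Plausible ranges for parameters whose study values are appendix-only.
# Each entry: [low, high] plus a one-line justification. The synthetic
# generator draws uniformly within these ranges, then enforces only the
# orderings the study states (broad-spectrum regimen coverage above the two
# narrow regimens; ICU daily cost above ward; uncovered-infection outcomes
# worse than covered; deterioration worse than improvement).
coverage_narrow: # ceftriaxone+gentamicin, ampicillin+gentamicin
  range: [0.45, 0.70]
  why: typical empiric coverage of first-line combinations against LMIC bloodstream isolates
coverage_broad: # meropenem+vancomycin; drawn above narrow regimens
  range: [0.80, 0.95]
  why: carbapenem + glycopeptide covers most bloodstream pathogens
stepup_drug_cost_per_day:
  range: [30.0, 80.0]
  why: escalation to carbapenem- or colistin-based therapy
stepdown_drug_cost_per_day:
  range: [0.5, 5.0]
  why: de-escalation to narrow-spectrum generics
icu_cost_per_day:
  range: [250.0, 500.0]
  why: LMIC tertiary-hospital ICU bed-day cost estimates
ward_cost_per_day:
  range: [30.0, 80.0]
  why: general medicine ward bed-day cost, LMIC tertiary hospital
amr_cost_per_course:
  range: [10.0, 60.0]
  why: externality cost of resistance per full antibiotic course (literature estimates)
definitive_days:
  range: [5, 10]
  why: usual definitive-therapy duration for bloodstream infection
prob_improve_covered:
  range: [0.55, 0.80]
  why: most appropriately treated bacteraemia improves on therapy
prob_deteriorate_covered:
  range: [0.05, 0.15]
  why: residual deterioration despite adequate coverage
prob_deteriorate_uncovered:
  range: [0.35, 0.60]
  why: uncovered bloodstream infection frequently progresses to ICU care
prob_improve_uninfected:
  range: [0.70, 0.90]
  why: patients without true bacterial infection mostly improve
prob_deteriorate_uninfected:
  range: [0.02, 0.10]
  why: non-bacterial illness occasionally deteriorates
switch_stepup_clinical:
  range: [0.10, 0.25]
  why: blind escalation on clinical grounds is uncommon but real
switch_stepdown_clinical:
  range: [0.05, 0.15]
  why: blind de-escalation without culture data is rare
switch_stepdown_weight_positive:
  range: [0.15, 0.45]
  why: share of covered culture-positive patients de-escalated on susceptibility results
mortality_improve_covered:
  range: [0.01, 0.04]
  why: low residual mortality after improvement on adequate therapy
mortality_deteriorate_covered:
  range: [0.20, 0.35]
  why: ICU-level bacteraemia mortality despite coverage
mortality_deteriorate_uncovered:
  range: [0.45, 0.65]
  why: uncovered deteriorating bloodstream infection is frequently fatal
mortality_uninfected_scale:
  range: [0.3, 0.6]
  why: uninfected trajectories carry a fraction of the covered-infection mortality
los_improve:
  range: [4, 7]
  why: short stay after prompt improvement
los_unchanged:
  range: [7, 11]
  why: intermediate stay when condition is static
los_deteriorate:
  range: [10, 18]
  why: ICU admission prolongs stay
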