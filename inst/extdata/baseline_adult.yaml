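# Baseline model configuration, adult population (2022 USD).
# Values tagged `paper` in `sources` are printed study inputs; values tagged
# `placeholder` stand in for appendix-only inputs and are documented in
# placeholder_ranges.yaml. Do not edit paper-tagged values.
population: adult
test:
  prevalence: 0.40
  sensitivity: 0.80
  false_positive: 0.05
  bottles_per_patient: 2
  empiric_days: 3
regimens:
  ceftriaxone_gentamicin:
    name: ceftriaxone_gentamicin
    drug_cost_per_day: 1.76
    coverage: 0.60
    stepup_drug_cost_per_day: 35.16
    stepdown_drug_cost_per_day: 1.00
  ampicillin_gentamicin:
    name: ampicillin_gentamicin
    drug_cost_per_day: 3.04
    coverage: 0.55
    stepup_drug_cost_per_day: 35.16
    stepdown_drug_cost_per_day: 1.00
  meropenem_vancomycin:
    name: meropenem_vancomycin
    drug_cost_per_day: 35.16
    coverage: 0.85
    stepup_drug_cost_per_day: 60.00
    stepdown_drug_cost_per_day: 3.04
transitions:
  clinical_change:
    infected_covered:
      improve: 0.70
      unchanged: 0.20
      deteriorate: 0.10
    infected_uncovered:
      improve: 0.20
      unchanged: 0.30
      deteriorate: 0.50
    uninfected:
      improve: 0.80
      unchanged: 0.15
      deteriorate: 0.05
  switch:
    culture_positive:
      step_up: 0.50
      step_down: 0.15
      no_change: 0.35
    clinical_only:
      step_up: 0.15
      step_down: 0.10
      no_change: 0.75
costs:
  culture_positive_bottle: 31.90
  culture_negative_bottle: 5.80
  maintenance_per_sample: 34.53
  maintenance_unit: bottle
  icu_cost_per_day: 380.00
  ward_cost_per_day: 48.00
  amr_cost_per_course: 28.00
  annual_fixed_lab_cost: 131697
  annual_samples: 3813
outcomes:
  mortality:
    infected_covered:
      improve: 0.02
      unchanged: 0.08
      deteriorate: 0.30
    infected_uncovered:
      improve: 0.05
      unchanged: 0.18
      deteriorate: 0.55
    uninfected:
      improve: 0.01
      unchanged: 0.03
      deteriorate: 0.20
  los_days:
    infected_covered:
      improve: 5
      unchanged: 8
      deteriorate: 12
    infected_uncovered:
      improve: 7
      unchanged: 10
      deteriorate: 16
    uninfected:
      improve: 4
      unchanged: 6
      deteriorate: 10
daly:
  years_lost_per_death: 11
  disability_weight: 0.133
  days_per_year: 365
  cohort_size: 1000
  wtp_per_daly: 500
policy:
  definitive_days: 7
  fp_branch_policy: informed
  coverage_stepup_rule: one_minus_coverage
  blind_stepup_covers: true
sources:
  test.prevalence: paper
  test.sensitivity: paper
  test.false_positive: paper
  test.bottles_per_patient: paper
  test.empiric_days: paper
  regimens.ceftriaxone_gentamicin.drug_cost_per_day: paper
  regimens.ampicillin_gentamicin.drug_cost_per_day: paper
  regimens.meropenem_vancomycin.drug_cost_per_day: paper
  regimens.ceftriaxone_gentamicin.coverage: placeholder
  regimens.ampicillin_gentamicin.coverage: placeholder
  regimens.meropenem_vancomycin.coverage: placeholder
  regimens.ceftriaxone_gentamicin.stepup_drug_cost_per_day: placeholder
  regimens.ampicillin_gentamicin.stepup_drug_cost_per_day: placeholder
  regimens.meropenem_vancomycin.stepup_drug_cost_per_day: placeholder
  regimens.ceftriaxone_gentamicin.stepdown_drug_cost_per_day: placeholder
  regimens.ampicillin_gentamicin.stepdown_drug_cost_per_day: placeholder
  regimens.meropenem_vancomycin.stepdown_drug_cost_per_day: placeholder
  transitions.clinical_change.infected_covered: placeholder
  transitions.clinical_change.infected_uncovered: placeholder
  transitions.clinical_change.uninfected: placeholder
  transitions.switch.culture_positive: placeholder
  transitions.switch.clinical_only: placeholder
  costs.culture_positive_bottle: paper
  costs.culture_negative_bottle: paper
  costs.maintenance_per_sample: paper
  costs.icu_cost_per_day: placeholder
  costs.ward_cost_per_day: placeholder
  costs.amr_cost_per_course: placeholder
  costs.annual_fixed_lab_cost: paper
  costs.annual_samples: paper
  outcomes.mortality: placeholder
  outcomes.los_days: placeholder
  daly.years_lost_per_death: paper
  daly.disability_weight: paper
  daly.days_per_year: placeholder
  daly.cohort_size: paper
  daly.wtp_per_daly: paper
  policy.definitive_days: placeholder
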