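{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "labcea parameter set",
  "description": "Full model parameterisation for the two-arm decision-tree cost-effectiveness analysis. Money is decimal 2022 USD; probabilities are decimals in [0,1]. Every transition distribution must sum to 1 within 1e-9.",
  "type": "object",
  "required": ["population", "test", "regimens", "transitions", "costs", "outcomes", "daly", "policy"],
  "additionalProperties": false,
  "$defs": {
    "prob": {"type": "number", "minimum": 0, "maximum": 1},
    "usd": {"type": "number", "minimum": 0},
    "change_dist": {
      "type": "object",
      "required": ["improve", "unchanged", "deteriorate"],
      "additionalProperties": false,
      "properties": {
        "improve": {"$ref": "#/$defs/prob"},
        "unchanged": {"$ref": "#/$defs/prob"},
        "deteriorate": {"$ref": "#/$defs/prob"}
      }
    },
    "switch_dist": {
      "type": "object",
      "required": ["step_up", "step_down", "no_change"],
      "additionalProperties": false,
      "properties": {
        "step_up": {"$ref": "#/$defs/prob"},
        "step_down": {"$ref": "#/$defs/prob"},
        "no_change": {"$ref": "#/$defs/prob"}
      }
    },
    "by_state": {
      "type": "object",
      "required": ["infected_covered", "infected_uncovered", "uninfected"],
      "additionalProperties": false,
      "properties": {
        "infected_covered": {"$ref": "#/$defs/change_dist"},
        "infected_uncovered": {"$ref": "#/$defs/change_dist"},
        "uninfected": {"$ref": "#/$defs/change_dist"}
      }
    },
    "value_by_change": {
      "type": "object",
      "required": ["improve", "unchanged", "deteriorate"],
      "additionalProperties": false,
      "properties": {
        "improve": {"type": "number", "minimum": 0},
        "unchanged": {"type": "number", "minimum": 0},
        "deteriorate": {"type": "number", "minimum": 0}
      }
    },
    "values_by_state": {
      "type": "object",
      "required": ["infected_covered", "infected_uncovered", "uninfected"],
      "additionalProperties": false,
      "properties": {
        "infected_covered": {"$ref": "#/$defs/value_by_change"},
        "infected_uncovered": {"$ref": "#/$defs/value_by_change"},
        "uninfected": {"$ref": "#/$defs/value_by_change"}
      }
    },
    "regimen": {
      "type": "object",
      "required": ["name", "drug_cost_per_day", "coverage", "stepup_drug_cost_per_day", "stepdown_drug_cost_per_day"],
      "additionalProperties": false,
      "properties": {
        "name": {"type": "string"},
        "drug_cost_per_day": {"$ref": "#/$defs/usd"},
        "coverage": {"$ref": "#/$defs/prob"},
        "stepup_drug_cost_per_day": {"$ref": "#/$defs/usd"},
        "stepdown_drug_cost_per_day": {"$ref": "#/$defs/usd"}
      }
    }
  },
  "properties": {
    "population": {"enum": ["adult", "under4"]},
    "test": {
      "type": "object",
      "required": ["prevalence", "sensitivity", "false_positive", "bottles_per_patient", "empiric_days"],
      "additionalProperties": false,
      "properties": {
        "prevalence": {"$ref": "#/$defs/prob"},
        "sensitivity": {"$ref": "#/$defs/prob"},
        "false_positive": {"$ref": "#/$defs/prob"},
        "bottles_per_patient": {"enum": [2, 4]},
        "empiric_days": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "regimens": {
      "type": "object",
      "required": ["ceftriaxone_gentamicin", "ampicillin_gentamicin", "meropenem_vancomycin"],
      "additionalProperties": false,
      "properties": {
        "ceftriaxone_gentamicin": {"$ref": "#/$defs/regimen"},
        "ampicillin_gentamicin": {"$ref": "#/$defs/regimen"},
        "meropenem_vancomycin": {"$ref": "#/$defs/regimen"}
      }
    },
    "transitions": {
      "type": "object",
      "required": ["clinical_change", "switch"],
      "additionalProperties": false,
      "properties": {
        "clinical_change": {"$ref": "#/$defs/by_state"},
        "switch": {
          "type": "object",
          "required": ["culture_positive", "clinical_only"],
          "additionalProperties": false,
          "properties": {
            "culture_positive": {"$ref": "#/$defs/switch_dist"},
            "clinical_only": {"$ref": "#/$defs/switch_dist"}
          }
        }
      }
    },
    "costs": {
      "type": "object",
      "required": ["culture_positive_bottle", "culture_negative_bottle", "maintenance_per_sample", "maintenance_unit", "icu_cost_per_day", "ward_cost_per_day", "amr_cost_per_course", "annual_fixed_lab_cost", "annual_samples"],
      "additionalProperties": false,
      "properties": {
        "culture_positive_bottle": {"$ref": "#/$defs/usd"},
        "culture_negative_bottle": {"$ref": "#/$defs/usd"},
        "maintenance_per_sample": {"$ref": "#/$defs/usd"},
        "maintenance_unit": {"enum": ["bottle", "set"]},
        "icu_cost_per_day": {"$ref": "#/$defs/usd"},
        "ward_cost_per_day": {"$ref": "#/$defs/usd"},
        "amr_cost_per_course": {"$ref": "#/$defs/usd"},
        "annual_fixed_lab_cost": {"$ref": "#/$defs/usd"},
        "annual_samples": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "outcomes": {
      "type": "object",
      "required": ["mortality", "los_days"],
      "additionalProperties": false,
      "properties": {
        "mortality": {"$ref": "#/$defs/by_state"},
        "los_days": {"$ref": "#/$defs/values_by_state"}
      }
    },
    "daly": {
      "type": "object",
      "required": ["years_lost_per_death", "disability_weight", "days_per_year", "cohort_size", "wtp_per_daly"],
      "additionalProperties": false,
      "properties": {
        "years_lost_per_death": {"type": "number", "exclusiveMinimum": 0},
        "disability_weight": {"$ref": "#/$defs/prob"},
        "days_per_year": {"type": "number", "exclusiveMinimum": 0},
        "cohort_size": {"type": "number", "exclusiveMinimum": 0},
        "wtp_per_daly": {"$ref": "#/$defs/usd"}
      }
    },
    "policy": {
      "type": "object",
      "required": ["definitive_days"],
      "additionalProperties": false,
      "properties": {
        "definitive_days": {"type": "number", "exclusiveMinimum": 0},
        "fp_branch_policy": {"enum": ["informed"]},
        "coverage_stepup_rule": {"enum": ["one_minus_coverage"]},
        "blind_stepup_covers": {"type": "boolean"}
      }
    },
    "sources": {
      "type": "object",
      "additionalProperties": {"enum": ["paper", "placeholder"]}
    }
  }
}
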