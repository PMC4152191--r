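{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "depcohort scenario configuration",
  "type": "object",
  "required": ["scenario", "occupation", "states", "initial", "transitions", "costs", "utilities"],
  "properties": {
    "scenario": {"enum": ["absenteeism", "presenteeism"]},
    "occupation": {"enum": ["blue", "white", "pooled"]},
    "states": {
      "type": "array",
      "minItems": 2,
      "items": {
        "type": "object",
        "required": ["name", "alive", "depressed", "in_treatment", "absorbing", "employed"],
        "properties": {
          "name": {"type": "string"},
          "alive": {"type": "boolean"},
          "depressed": {"type": "boolean"},
          "in_treatment": {"type": "boolean"},
          "absorbing": {"type": "boolean"},
          "employed": {"type": "boolean"}
        }
      }
    },
    "initial": {
      "type": "object",
      "description": "state name -> probability; sums to 1; absorbing states 0",
      "additionalProperties": {"type": "number", "minimum": 0, "maximum": 1}
    },
    "transitions": {
      "type": "object",
      "required": ["remission_treated_12m", "remission_untreated_12m",
                   "relapse_treated_12m", "relapse_untreated_12m",
                   "treatment_initiation_12m", "baseline_mortality_annual",
                   "suicide_mortality_multiplier", "early_retirement_annual",
                   "cohort_start_age", "sex_mix"],
      "properties": {
        "remission_treated_12m": {"type": "number", "minimum": 0, "maximum": 1},
        "remission_untreated_12m": {"type": "number", "minimum": 0, "maximum": 1},
        "relapse_treated_12m": {"type": "number", "minimum": 0, "maximum": 1},
        "relapse_untreated_12m": {"type": "number", "minimum": 0, "maximum": 1},
        "treatment_initiation_12m": {"type": "number", "minimum": 0, "maximum": 1},
        "baseline_mortality_annual": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["age_lo", "age_hi", "male", "female"],
            "properties": {
              "age_lo": {"type": "number"},
              "age_hi": {"type": "number"},
              "male": {"type": "number", "minimum": 0, "maximum": 1},
              "female": {"type": "number", "minimum": 0, "maximum": 1}
            }
          }
        },
        "suicide_mortality_multiplier": {"type": "number", "minimum": 1},
        "early_retirement_annual": {"type": "number", "minimum": 0, "maximum": 1},
        "cohort_start_age": {"type": "number", "exclusiveMinimum": 0},
        "sex_mix": {"type": "number", "minimum": 0, "maximum": 1,
                    "description": "proportion female"}
      }
    },
    "costs": {
      "type": "object",
      "required": ["absenteeism_days_per_cycle", "presenteeism_days_per_cycle",
                   "daily_wage", "annual_salary", "turnover_probability_12m",
                   "turnover_cost_multiplier_range", "service_contacts_per_year",
                   "service_unit_costs", "antidepressant_use_prob_2wk",
                   "antidepressant_script_cost_3m"],
      "properties": {
        "absenteeism_days_per_cycle": {"type": "number", "minimum": 0},
        "presenteeism_days_per_cycle": {"type": "number", "minimum": 0},
        "daily_wage": {"type": "number", "minimum": 0},
        "annual_salary": {"type": "number", "minimum": 0},
        "turnover_probability_12m": {"type": "number", "minimum": 0, "maximum": 1},
        "turnover_probability_12m_not_depressed": {"type": "number", "minimum": 0, "maximum": 1},
        "turnover_cost_multiplier_range": {
          "type": "array", "items": {"type": "number"}, "minItems": 2, "maxItems": 2
        },
        "service_contacts_per_year": {"type": "object", "additionalProperties": {"type": "number", "minimum": 0}},
        "service_unit_costs": {"type": "object", "additionalProperties": {"type": "number", "minimum": 0}},
        "antidepressant_use_prob_2wk": {"type": "number", "minimum": 0, "maximum": 1},
        "antidepressant_script_cost_3m": {"type": "number", "minimum": 0}
      }
    },
    "utilities": {
      "type": "object",
      "additionalProperties": {"type": "number", "minimum": 0, "maximum": 1}
    },
    "psa": {
      "type": "object",
      "description": "parameter path -> distribution spec",
      "additionalProperties": {
        "type": "object",
        "required": ["family"],
        "properties": {
          "family": {"enum": ["beta", "gamma", "uniform", "fixed"]},
          "mean": {"type": "number"},
          "se": {"type": "number", "exclusiveMinimum": 0},
          "low": {"type": "number"},
          "high": {"type": "number"}
        }
      }
    },
    "run": {
      "type": "object",
      "properties": {
        "cohort_size": {"type": "integer", "minimum": 1, "default": 1000},
        "cycle_length": {"type": "number", "exclusiveMinimum": 0, "default": 0.25},
        "horizon": {"type": "integer", "minimum": 1, "default": 20},
        "annual_discount_rate": {"type": "number", "minimum": 0, "exclusiveMaximum": 1, "default": 0.03},
        "half_cycle_correction": {"type": "boolean", "default": false},
        "seed": {"type": "integer", "default": 1}
      }
    }
  }
}
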