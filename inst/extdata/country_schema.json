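{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "snakeburden country configuration",
  "description": "Complete input parameter set for one country. Any entry marked 'uncertain' is either a bare number (a fixed parameter) or an object {point, low, high, family} with low <= point <= high; family is one of beta, gamma, lognormal, dirichlet_share, uniform, fixed and defaults by parameter kind. Unknown keys anywhere are rejected.",
  "type": "object",
  "additionalProperties": false,
  "required": ["schema_version", "name", "population", "profile", "probabilities", "antivenom_courses", "lengths_of_stay", "unit_costs", "economics"],
  "properties": {
    "schema_version": {"const": 1},
    "name": {"type": "string"},
    "population": {"type": "number", "exclusiveMinimum": 0},
    "incidence": {"$ref": "#/$defs/uncertain", "description": "victims per 100,000 per year; exactly one of incidence/victims"},
    "victims": {"$ref": "#/$defs/uncertain", "description": "annual victims; exactly one of incidence/victims"},
    "profile": {
      "type": "array", "minItems": 1,
      "items": {
        "type": "object", "additionalProperties": false,
        "required": ["sex", "age_low", "age_high", "share", "mean_age_at_death"],
        "properties": {
          "sex": {"enum": ["female", "male"]},
          "age_low": {"type": "number", "minimum": 0},
          "age_high": {"type": "number"},
          "share": {"type": "number", "minimum": 0, "maximum": 1},
          "mean_age_at_death": {"type": "number", "minimum": 0}
        }
      },
      "description": "shares must sum to 1; strata of one sex must not overlap in age"
    },
    "probabilities": {
      "type": "object", "additionalProperties": false,
      "required": ["p_conventional_first", "p_switch_to_conventional", "p_indicated", "p_adr", "p_death_treated", "p_amputation_survivor"],
      "properties": {
        "p_conventional_first": {"$ref": "#/$defs/uncertain"},
        "p_switch_to_conventional": {"$ref": "#/$defs/uncertain"},
        "p_indicated": {"$ref": "#/$defs/uncertain"},
        "p_adr": {"$ref": "#/$defs/uncertain"},
        "p_death_treated": {"$ref": "#/$defs/uncertain"},
        "rr_death_untreated": {"$ref": "#/$defs/uncertain", "description": "default 2.33 [1.26, 4.06] lognormal"},
        "p_amputation_survivor": {"$ref": "#/$defs/uncertain"}
      }
    },
    "antivenom_courses": {"$ref": "#/$defs/uncertain", "description": "treatment courses available per year"},
    "lengths_of_stay": {
      "type": "object", "additionalProperties": false,
      "required": ["los_indicated", "los_not_indicated"],
      "properties": {
        "los_indicated": {"$ref": "#/$defs/uncertain"},
        "los_not_indicated": {"$ref": "#/$defs/uncertain"}
      }
    },
    "unit_costs": {
      "type": "object", "additionalProperties": false,
      "description": "all in local currency",
      "required": ["hospital_day", "antivenom_course", "antivenom_logistics", "adr_management", "amputation", "transport", "food_person_day"],
      "properties": {
        "hospital_day": {"$ref": "#/$defs/uncertain"},
        "antivenom_course": {"$ref": "#/$defs/uncertain"},
        "antivenom_logistics": {"$ref": "#/$defs/uncertain"},
        "adr_management": {"$ref": "#/$defs/uncertain"},
        "amputation": {"$ref": "#/$defs/uncertain"},
        "transport": {"$ref": "#/$defs/uncertain"},
        "food_person_day": {"$ref": "#/$defs/uncertain"}
      }
    },
    "economics": {
      "type": "object", "additionalProperties": false,
      "required": ["exchange_rate", "gdp_per_capita", "gdp_growth"],
      "properties": {
        "exchange_rate": {"type": "number", "exclusiveMinimum": 0, "description": "local currency units per 2019 USD"},
        "gdp_per_capita": {"type": "number", "exclusiveMinimum": 0, "description": "2019 USD"},
        "gdp_growth": {"$ref": "#/$defs/uncertain", "description": "fraction per year"},
        "discount_rate": {"$ref": "#/$defs/uncertain", "description": "default 0.03 [0, 0.06]; varied in one-way SA only"},
        "retirement_age": {"type": "number", "exclusiveMinimum": 0, "default": 60},
        "daily_income_divisor": {"type": "number", "exclusiveMinimum": 0, "default": 365}
      }
    }
  },
  "$defs": {
    "uncertain": {
      "oneOf": [
        {"type": "number"},
        {
          "type": "object", "additionalProperties": false,
          "required": ["point"],
          "properties": {
            "point": {"type": "number"},
            "low": {"type": "number"},
            "high": {"type": "number"},
            "family": {"enum": ["beta", "gamma", "lognormal", "dirichlet_share", "uniform", "fixed"]}
          }
        }
      ]
    }
  }
}
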