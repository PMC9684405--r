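{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "rascycle model/scenario configuration",
  "description": "Contract for YAML/JSON configurations accepted by read_model_config(). The in-package validator (validate_config) implements these checks.",
  "type": "object",
  "required": ["base_parameters", "pools"],
  "properties": {
    "base_parameters": {
      "type": "object",
      "description": "Wild-type reference constants (M, s units).",
      "additionalProperties": false,
      "properties": {
        "k_hyd_intrinsic": {"type": "number", "exclusiveMinimum": 0},
        "k_act_intrinsic": {"type": "number", "exclusiveMinimum": 0},
        "gef_kon": {"type": "number", "exclusiveMinimum": 0},
        "gef_koff": {"type": "number", "exclusiveMinimum": 0},
        "gef_kcat": {"type": "number", "exclusiveMinimum": 0},
        "gap_kon": {"type": "number", "exclusiveMinimum": 0},
        "gap_koff": {"type": "number", "exclusiveMinimum": 0},
        "gap_kcat": {"type": "number", "exclusiveMinimum": 0},
        "eff_kon": {"type": "number", "exclusiveMinimum": 0},
        "eff_koff": {"type": "number", "exclusiveMinimum": 0},
        "gef_total": {"type": "number", "minimum": 0},
        "gap_total": {"type": "number", "minimum": 0},
        "eff_total": {"type": "number", "minimum": 0},
        "ras_total": {"type": "number", "exclusiveMinimum": 0},
        "ras_production_total": {"type": "number", "exclusiveMinimum": 0},
        "t_half": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "pools": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["name", "isoform", "genotype", "abundance_fraction"],
        "properties": {
          "name": {"type": "string"},
          "isoform": {"enum": ["KRAS", "NRAS", "HRAS"]},
          "genotype": {"enum": ["WT", "G12C", "G12V"]},
          "abundance_fraction": {"type": "number", "minimum": 0, "maximum": 1}
        }
      },
      "description": "abundance_fraction values must sum to 1 (tolerance 1e-12)."
    },
    "egfri_link": {
      "type": "object",
      "properties": {
        "ic50_ug_per_ml": {"type": "number", "exclusiveMinimum": 0},
        "hill": {"type": "number", "exclusiveMinimum": 0},
        "max_inhibition": {"type": "number", "minimum": 0, "maximum": 1}
      }
    },
    "doses": {
      "type": "object",
      "properties": {
        "g12ci_nM": {
          "type": "array",
          "items": {"type": "number", "minimum": 0},
          "description": "first element must be 0 (vehicle)"
        },
        "egfri_ug_per_ml": {
          "type": "array",
          "items": {"type": "number", "minimum": 0},
          "description": "first element must be 0 (vehicle)"
        }
      }
    },
    "treatment": {
      "type": "object",
      "properties": {
        "g12ci": {
          "type": "object",
          "required": ["dose_nM"],
          "properties": {
            "name": {"type": "string"},
            "kinact_over_ki": {"type": "number", "exclusiveMinimum": 0},
            "dose_nM": {"type": "number", "minimum": 0}
          }
        },
        "egfri": {
          "type": "object",
          "description": "exactly one of dose_ug_per_ml or fraction",
          "properties": {
            "dose_ug_per_ml": {"type": "number", "minimum": 0},
            "fraction": {"type": "number", "minimum": 0, "maximum": 1}
          }
        },
        "perturbation": {
          "type": "object",
          "properties": {
            "nf1_kd": {"type": "number", "minimum": 0, "maximum": 1},
            "kras_kd": {"type": "number", "minimum": 0, "maximum": 1}
          }
        }
      }
    },
    "synthetic": {
      "type": "object",
      "properties": {
        "sigma": {"type": "number", "minimum": 0},
        "n_replicates": {"type": "integer", "minimum": 1},
        "link": {
          "type": "object",
          "properties": {
            "gamma": {"type": "number", "exclusiveMinimum": 0},
            "floor": {"type": "number", "minimum": 0, "exclusiveMaximum": 1}
          }
        },
        "perk": {
          "type": "object",
          "properties": {
            "hill": {"type": "number", "exclusiveMinimum": 0},
            "k_half_rel": {"type": "number", "exclusiveMinimum": 0}
          }
        }
      }
    },
    "seed": {"type": "integer"}
  }
}
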