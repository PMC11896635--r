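{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "spinhop model_system document",
  "type": "object",
  "required": ["modes", "electronic"],
  "additionalProperties": false,
  "properties": {
    "label": { "type": "string" },
    "modes": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["label", "frequency_cm1", "reduced_mass_amu"],
        "additionalProperties": false,
        "properties": {
          "label": { "type": "string" },
          "frequency_cm1": { "type": "number", "exclusiveMinimum": 0 },
          "reduced_mass_amu": { "type": "number", "exclusiveMinimum": 0 },
          "equilibrium": { "type": "number" }
        }
      }
    },
    "electronic": {
      "type": "object",
      "required": ["n_singlets", "n_triplets", "vertical_energies_eV"],
      "additionalProperties": false,
      "properties": {
        "n_singlets": { "type": "integer", "minimum": 1 },
        "n_triplets": { "type": "integer", "minimum": 0 },
        "vertical_energies_eV": {
          "type": "array", "items": { "type": "number" },
          "description": "length n_singlets + n_triplets; singlets ascending first, then triplets ascending"
        },
        "oscillator_strengths": {
          "type": "array", "items": { "type": "number", "minimum": 0 },
          "description": "length n_singlets - 1"
        },
        "intrastate_gradients_eV": {
          "type": "array",
          "items": { "type": "array", "items": { "type": "number" } },
          "description": "(n_singlets + n_triplets) rows x n_modes columns, eV per unit coordinate"
        },
        "interstate_couplings": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["state_a", "state_b", "mode", "value_eV"],
            "additionalProperties": false,
            "properties": {
              "state_a": { "type": "string" },
              "state_b": { "type": "string" },
              "mode": { "type": "string" },
              "value_eV": { "type": "number" }
            }
          }
        }
      }
    },
    "soc": {
      "type": "object",
      "required": ["couplings"],
      "additionalProperties": false,
      "properties": {
        "couplings": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["singlet", "triplet", "component", "re_cm1"],
            "additionalProperties": false,
            "properties": {
              "singlet": { "type": "string" },
              "triplet": { "type": "string" },
              "component": { "enum": [-1, 0, 1] },
              "re_cm1": { "type": "number" },
              "im_cm1": { "type": "number" }
            }
          }
        },
        "modulation": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["singlet", "triplet", "component", "coordinate"],
            "additionalProperties": false,
            "properties": {
              "singlet": { "type": "string" },
              "triplet": { "type": "string" },
              "component": { "enum": [-1, 0, 1] },
              "coordinate": { "type": "string" },
              "linear_cm1": { "type": "number" },
              "quadratic_cm1": { "type": "number" }
            }
          }
        }
      }
    }
  }
}
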