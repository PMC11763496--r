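{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "msbiotyper biotype report",
  "type": "object",
  "required": [
    "strains", "distinguishable", "min_rel", "n_common_ions",
    "n_distinct_common_mz", "n_distinctive_ions", "cell_similarity",
    "common_ions", "identified", "discrepancies", "missing_cells", "warnings"
  ],
  "properties": {
    "strains": {
      "type": "array", "items": {"type": "string"},
      "minItems": 2, "maxItems": 2
    },
    "distinguishable": {"type": "boolean"},
    "min_rel": {"type": "number", "minimum": 0, "maximum": 100},
    "n_common_ions": {"type": "integer", "minimum": 0},
    "n_distinct_common_mz": {"type": "integer", "minimum": 0},
    "n_distinctive_ions": {"type": "integer", "minimum": 0},
    "cell_similarity": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["medium", "period_days", "polarity", "n_a", "n_b",
                      "n_common", "n_symmetric_diff", "jaccard"],
        "properties": {
          "medium": {"enum": ["MEA", "PDA", "SDA"]},
          "period_days": {"enum": [7, 15, 22, 30]},
          "polarity": {"enum": ["positive", "negative"]},
          "jaccard": {"type": "number", "minimum": 0, "maximum": 1}
        }
      }
    },
    "common_ions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["medium", "period_days", "polarity", "mz",
                      "abundance_a", "abundance_b"],
        "properties": {
          "mz": {"type": "integer", "minimum": 125, "maximum": 2000},
          "abundance_a": {"type": "number", "exclusiveMinimum": 0, "maximum": 100},
          "abundance_b": {"type": "number", "exclusiveMinimum": 0, "maximum": 100}
        }
      }
    },
    "identified": {"type": "array", "items": {"type": "string"}},
    "discrepancies": {"type": "array"},
    "missing_cells": {"type": "array", "items": {"type": "string"}},
    "warnings": {"type": "array", "items": {"type": "string"}}
  }
}
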