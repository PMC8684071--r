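{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "haplodose pipeline report",
  "type": "object",
  "required": ["call", "reason", "qc"],
  "properties": {
    "fetalFraction": {
      "type": "object",
      "required": ["e", "sd", "nSites"],
      "properties": {
        "e": {"type": "number", "minimum": 0, "maximum": 1},
        "sd": {"type": "number", "minimum": 0},
        "nSites": {"type": "integer", "minimum": 1},
        "perKind": {"type": "object", "additionalProperties": {"type": "integer"}}
      }
    },
    "sValues": {
      "type": "object",
      "required": ["sMother", "sFather", "thresholds", "groups"],
      "properties": {
        "sMother": {"type": ["number", "null"]},
        "sFather": {"type": ["number", "null"]},
        "thresholds": {
          "type": "object",
          "properties": {
            "upper": {"type": "number", "exclusiveMinimum": 1},
            "lower": {"type": "number", "exclusiveMaximum": 1}
          }
        },
        "groups": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["label", "parent", "nLoci", "included"],
            "properties": {
              "label": {"enum": ["S1", "S2", "S3", "S4", "S5", "S6", "S7", "S8"]},
              "parent": {"enum": ["mother", "father"]},
              "nLoci": {"type": "integer", "minimum": 0},
              "FE": {"type": ["number", "null"]},
              "ME": {"type": ["number", "null"]},
              "PE": {"type": ["number", "null"]},
              "BE": {"type": ["number", "null"]},
              "factor": {"type": ["number", "null"]},
              "included": {"type": "boolean"}
            }
          }
        }
      }
    },
    "call": {
      "type": "object",
      "required": ["maternalInheritance", "paternalInheritance", "overall"],
      "properties": {
        "maternalInheritance": {"enum": ["PATHOGENIC", "WILD_TYPE", "INCONCLUSIVE"]},
        "paternalInheritance": {"enum": ["PATHOGENIC", "WILD_TYPE", "INCONCLUSIVE"]},
        "overall": {"enum": ["Affected", "Maternal mutation carriers", "Paternal mutation carriers", "N", "Inconclusive"]}
      }
    },
    "reason": {"type": "string"},
    "qc": {
      "type": "array",
      "items": {
        "type": "object",
        "properties": {
          "stage": {"type": "string"},
          "sitesIn": {"type": "integer"},
          "sitesOut": {"type": "integer"},
          "reason": {"type": "string"}
        }
      }
    }
  }
}
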