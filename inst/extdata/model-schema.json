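{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "cellchains compartment model configuration",
  "type": "object",
  "properties": {
    "N": {"type": "integer", "minimum": 1,
          "description": "number of compartments (optional; checked against the rate arrays)"},
    "lambda": {"$ref": "#/$defs/rates", "description": "self-renewal rates"},
    "s": {"$ref": "#/$defs/rates", "description": "symmetric-division rates (last entry must be 0)"},
    "a": {"$ref": "#/$defs/rates", "description": "asymmetric-division rates (last entry must be 0)"},
    "nu": {"$ref": "#/$defs/rates", "description": "forward differentiation rates (last entry must be 0)"},
    "xi": {"$ref": "#/$defs/rates", "description": "backward differentiation rates (first entry must be 0)"},
    "mu": {"$ref": "#/$defs/rates", "description": "death rates"},
    "label": {"type": "string"}
  },
  "required": ["lambda", "mu"],
  "additionalProperties": false,
  "$defs": {
    "rates": {
      "type": "array",
      "items": {"type": "number", "minimum": 0},
      "minItems": 1
    }
  }
}
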