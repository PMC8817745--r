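{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "HubScreen screening report",
  "type": "object",
  "required": ["tool", "version", "parameters", "overlap", "central_node",
               "excluded", "critical", "roles"],
  "properties": {
    "tool": {"type": "string"},
    "version": {"type": "string"},
    "parameters": {
      "type": "object",
      "required": ["source", "k", "tie_policy", "score_threshold", "seed"]
    },
    "overlap": {
      "type": "object",
      "required": ["k", "n_common", "overlap_percent",
                   "specific_a", "specific_b"],
      "properties": {
        "k": {"type": "integer"},
        "n_common": {"type": "integer"},
        "overlap_percent": {"type": "number", "minimum": 0, "maximum": 100},
        "specific_a": {"type": "array", "items": {"type": "string"}},
        "specific_b": {"type": "array", "items": {"type": "string"}}
      }
    },
    "central_node": {"type": "string"},
    "excluded": {
      "type": "object",
      "additionalProperties": {
        "enum": ["isolated_all_maps", "regulated_only", "generic_central"]
      }
    },
    "critical": {
      "type": "object",
      "additionalProperties": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["map", "sign"],
          "properties": {
            "map": {"enum": ["expression", "activation", "inhibition"]},
            "sign": {"enum": ["positive", "negative", "unspecified"]}
          }
        }
      }
    },
    "roles": {"type": "array"}
  }
}
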