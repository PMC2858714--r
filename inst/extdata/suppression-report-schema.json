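{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Suppression report",
  "type": "object",
  "required": ["threshold_label", "records_total", "records_suppressed",
               "percent_suppressed", "areas"],
  "properties": {
    "threshold_label": {"type": "string", "enum": ["0%", "5%", "20%"]},
    "records_total": {"type": "integer", "minimum": 0},
    "records_suppressed": {"type": "integer", "minimum": 0},
    "percent_suppressed": {"type": "number", "minimum": 0, "maximum": 100},
    "areas": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["area", "n_records", "flagged"],
        "properties": {
          "area": {"type": "string"},
          "n_records": {"type": "integer", "minimum": 0},
          "pop": {"type": "number"},
          "probability": {"type": ["number", "null"]},
          "flagged": {"type": "boolean"}
        }
      }
    }
  }
}
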