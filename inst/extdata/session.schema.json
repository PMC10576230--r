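{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/pdtrace/session.schema.json",
  "title": "pdtrace session log",
  "description": "One participant's full motor-screening record: demographics, device screen geometry, three ribbon-tracing mouse trials (line, sine, spiral) and three keyboard tapping trials (constant, alternating, random).",
  "type": "object",
  "required": ["session_id", "demographics", "screen", "mouse_trials", "keyboard_trials"],
  "properties": {
    "session_id": { "type": "string", "minLength": 1 },
    "demographics": {
      "type": "object",
      "required": ["pd_status"],
      "properties": {
        "pd_status": { "type": "boolean" },
        "age": { "type": ["integer", "null"], "minimum": 18, "maximum": 120 },
        "gender": { "enum": ["male", "female", "other", "unspecified"] },
        "race": { "enum": ["white", "asian", "american_indian_alaska_native", "other", "unspecified"] }
      }
    },
    "screen": {
      "type": "object",
      "required": ["width", "height"],
      "properties": {
        "width": { "type": "integer", "minimum": 1 },
        "height": { "type": "integer", "minimum": 1 }
      }
    },
    "mouse_trials": {
      "type": "array",
      "minItems": 3,
      "maxItems": 3,
      "items": {
        "type": "object",
        "required": ["spec", "samples"],
        "properties": {
          "spec": {
            "type": "object",
            "required": ["shape", "margin_frac", "base_y_frac", "amplitude_frac", "n_periods", "n_turns", "half_width_frac"],
            "properties": {
              "shape": { "enum": ["line", "sine", "spiral"] },
              "margin_frac": { "type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 0.5 },
              "base_y_frac": { "type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1 },
              "amplitude_frac": { "type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1 },
              "n_periods": { "type": "integer", "minimum": 1 },
              "n_turns": { "type": "integer", "minimum": 1 },
              "half_width_frac": { "type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1 }
            }
          },
          "samples": {
            "type": "array",
            "minItems": 2,
            "items": {
              "type": "object",
              "required": ["x", "y", "t", "inside"],
              "properties": {
                "x": { "type": "number" },
                "y": { "type": "number" },
                "t": { "type": "integer", "minimum": 0 },
                "inside": { "type": "boolean" }
              }
            }
          }
        }
      }
    },
    "keyboard_trials": {
      "type": "array",
      "minItems": 3,
      "maxItems": 3,
      "items": {
        "type": "object",
        "required": ["level", "timeout_ms", "prompts"],
        "properties": {
          "level": { "enum": ["constant", "alternating", "random"] },
          "timeout_ms": { "type": "integer", "minimum": 1 },
          "prompts": {
            "type": "array",
            "minItems": 10,
            "maxItems": 10,
            "items": {
              "type": "object",
              "required": ["prompted_key", "resolved", "presses"],
              "properties": {
                "prompted_key": { "type": "string", "minLength": 1, "maxLength": 1 },
                "resolved": { "type": "boolean" },
                "response_time": { "type": ["integer", "null"], "minimum": 0 },
                "presses": {
                  "type": "array",
                  "items": {
                    "type": "object",
                    "required": ["key", "t"],
                    "properties": {
                      "key": { "type": "string", "minLength": 1, "maxLength": 1 },
                      "t": { "type": "integer", "minimum": 0 }
                    }
                  }
                }
              }
            }
          }
        }
      }
    }
  }
}
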