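{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "neurodyn model specification",
  "type": "object",
  "properties": {
    "populations": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "properties": {
          "name": { "type": "string", "pattern": "^[A-Za-z_][A-Za-z0-9_]*$" },
          "size": { "type": "integer", "minimum": 1 },
          "equations": {
            "description": "Equation text in the model dialect, or the name of a packaged population object",
            "oneOf": [
              { "type": "string" },
              { "type": "array", "items": { "type": "string" } }
            ]
          },
          "mechanism_list": { "type": "array", "items": { "type": "string" } },
          "parameters": { "$ref": "#/$defs/parameters" }
        },
        "required": ["equations"]
      }
    },
    "connections": {
      "type": "array",
      "items": {
        "type": "object",
        "properties": {
          "source": { "type": "string" },
          "target": { "type": "string" },
          "mechanism_list": { "type": "array", "items": { "type": "string" } },
          "parameters": { "$ref": "#/$defs/parameters" }
        },
        "required": ["source", "target"]
      }
    },
    "mechanisms": {
      "description": "Inline mechanism definitions (equation text); these shadow same-named library files",
      "type": "object",
      "additionalProperties": {
        "oneOf": [
          { "type": "string" },
          { "type": "array", "items": { "type": "string" } }
        ]
      }
    }
  },
  "required": ["populations"],
  "$defs": {
    "parameters": {
      "type": "object",
      "additionalProperties": {
        "oneOf": [
          { "type": "number" },
          { "type": "array", "items": { "type": "number" } },
          {
            "type": "object",
            "description": "connectivity matrix, rows = target cells, columns = source cells",
            "properties": {
              "matrix": {
                "type": "array",
                "items": { "type": "array", "items": { "type": "number" } }
              }
            },
            "required": ["matrix"]
          }
        ]
      }
    }
  }
}
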