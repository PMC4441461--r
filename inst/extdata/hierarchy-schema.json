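{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "ahpbr/hierarchy-schema.json",
  "title": "AHP decision hierarchy model file",
  "type": "object",
  "required": ["goal", "objectives", "alternatives"],
  "properties": {
    "goal": {
      "type": "string",
      "minLength": 1,
      "description": "Label of the decision goal (single root of the hierarchy)."
    },
    "objectives": {
      "type": "array",
      "minItems": 1,
      "items": { "$ref": "#/definitions/node" },
      "description": "Top-level objectives; each may nest children to any depth."
    },
    "alternatives": {
      "type": "array",
      "minItems": 2,
      "items": { "type": "string", "minLength": 1 },
      "description": "Ordered decision alternatives, compared under every leaf objective."
    },
    "context": {
      "type": "string",
      "description": "Free-text decision context."
    }
  },
  "additionalProperties": false,
  "definitions": {
    "node": {
      "oneOf": [
        { "type": "string", "minLength": 1 },
        {
          "type": "object",
          "required": ["name"],
          "properties": {
            "name": { "type": "string", "minLength": 1 },
            "children": {
              "type": "array",
              "items": { "$ref": "#/definitions/node" }
            }
          },
          "additionalProperties": false
        }
      ]
    }
  }
}
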