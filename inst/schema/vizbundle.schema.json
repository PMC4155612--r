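{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "famdev-vizbundle",
  "title": "famdev visualization bundle",
  "description": "Data contract between the famdev analysis pipeline and any visualization front-end. Positions are 1-based reference positions; distances are in Angstrom; characteristic order is identical across meta.characteristics, histograms and conservation (histogram left-to-right corresponds to heat-map top-to-bottom).",
  "type": "object",
  "required": ["meta", "histograms", "stacks", "conservation", "filters"],
  "properties": {
    "meta": {
      "type": "object",
      "required": ["reference_id", "L", "characteristics", "mode", "position_base", "distance_unit"],
      "properties": {
        "reference_id": {"type": "string"},
        "reference_sequence": {"type": "string"},
        "L": {"type": "integer", "minimum": 1},
        "characteristics": {"type": "array", "items": {"type": "string"}},
        "classes": {"type": "array", "items": {"type": "string"}},
        "mode": {"enum": ["pc1", "indices"]},
        "position_base": {"const": 1},
        "distance_unit": {"const": "angstrom"},
        "generator": {"type": "string"}
      }
    },
    "histograms": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["characteristic_id", "bin_edges", "counts", "n_clamped_low", "n_clamped_high"],
        "properties": {
          "characteristic_id": {"type": "string"},
          "bin_edges": {"type": "array", "items": {"type": "number"}},
          "counts": {"type": "array", "items": {"type": "integer", "minimum": 0}},
          "n_clamped_low": {"type": "integer", "minimum": 0},
          "n_clamped_high": {"type": "integer", "minimum": 0}
        }
      }
    },
    "stacks": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["position", "positive", "negative"],
        "properties": {
          "position": {"type": "integer", "minimum": 1},
          "positive": {"$ref": "#/definitions/segments"},
          "negative": {"$ref": "#/definitions/segments"}
        }
      }
    },
    "conservation": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["characteristic_id", "raw", "display"],
        "properties": {
          "characteristic_id": {"type": "string"},
          "raw": {"type": "array", "items": {"type": ["number", "null"]}},
          "display": {"type": "array", "items": {"type": ["number", "null"], "minimum": 0, "maximum": 1}}
        }
      }
    },
    "chords": {
      "type": ["object", "null"],
      "required": ["d_lo", "d_hi", "bundles"],
      "properties": {
        "d_lo": {"type": "number"},
        "d_hi": {"type": "number"},
        "bundles": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["target_start", "target_end", "min_distance", "brightness_rank"],
            "properties": {
              "target_start": {"type": "integer", "minimum": 1},
              "target_end": {"type": "integer", "minimum": 1},
              "min_distance": {"type": "number", "minimum": 0},
              "brightness_rank": {"type": "integer", "minimum": 0}
            }
          }
        }
      }
    },
    "proximity_histogram": {
      "type": ["object", "null"],
      "required": ["bin_edges", "counts"],
      "properties": {
        "bin_edges": {"type": "array", "items": {"type": "number", "minimum": 0}},
        "counts": {"type": "array", "items": {"type": "integer", "minimum": 0}}
      }
    },
    "focus": {
      "type": ["object", "null"],
      "required": ["start", "end"],
      "properties": {
        "start": {"type": "integer", "minimum": 1},
        "end": {"type": "integer", "minimum": 1}
      }
    },
    "filters": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["characteristic_id", "lo", "hi"],
        "properties": {
          "characteristic_id": {"type": "string"},
          "lo": {"type": "number"},
          "hi": {"type": "number"}
        }
      }
    }
  },
  "definitions": {
    "segments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["characteristic", "magnitude", "raw"],
        "properties": {
          "characteristic": {"type": "string"},
          "magnitude": {"type": "number", "minimum": 0, "maximum": 3},
          "raw": {"type": "number"}
        }
      }
    }
  }
}
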