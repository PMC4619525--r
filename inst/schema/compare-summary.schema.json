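{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "hospsample compare summary report",
  "type": "object",
  "required": ["meta", "error_summary", "head_to_head"],
  "properties": {
    "meta": {
      "type": "object",
      "required": ["package", "version", "seed", "n_reps", "n_batches",
                   "population_size", "strategies", "products", "scenarios"],
      "properties": {
        "package": {"const": "hospsample"},
        "version": {"type": "string"},
        "seed": {"type": "integer"},
        "n_reps": {"type": "integer", "minimum": 1},
        "n_batches": {"type": "integer", "minimum": 1},
        "population_size": {"type": "integer", "minimum": 1},
        "holdout_only": {"type": "boolean"},
        "strategies": {
          "type": "array",
          "items": {"enum": ["larg", "maxvar", "rand", "regvar", "2reg"]}
        },
        "products": {
          "type": "array",
          "items": {"enum": ["rbc", "ffp", "plt"]}
        },
        "scenarios": {"type": "object"}
      }
    },
    "error_summary": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["scenario", "strategy", "product", "metric", "median",
                     "mean", "centile_2.5", "centile_97.5"],
        "properties": {
          "scenario": {"type": "string"},
          "strategy": {"enum": ["larg", "maxvar", "rand", "regvar", "2reg"]},
          "product": {"enum": ["rbc", "ffp", "plt"]},
          "metric": {"enum": ["hospital", "national"]},
          "median": {"type": "number", "minimum": 0},
          "mean": {"type": "number", "minimum": 0},
          "centile_2.5": {"type": "number", "minimum": 0},
          "centile_97.5": {"type": "number", "minimum": 0},
          "batch_sd_median": {"type": "number", "minimum": 0},
          "failed": {"type": "integer", "minimum": 0},
          "n_reps_total": {"type": "integer", "minimum": 1}
        }
      }
    },
    "head_to_head": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["scenario", "random_strategy", "purposive_strategy",
                     "product", "metric", "pct_outperform"],
        "properties": {
          "random_strategy": {"enum": ["rand", "regvar", "2reg"]},
          "purposive_strategy": {"enum": ["maxvar", "larg"]},
          "pct_outperform": {"type": "number", "minimum": 0, "maximum": 100}
        }
      }
    }
  }
}
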