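{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "stereomotion experiment report bundle",
  "type": "object",
  "required": ["config_hash", "seed", "decoding", "behavior", "classification"],
  "properties": {
    "config_hash": { "type": "string" },
    "seed": { "type": "integer" },
    "decoding": {
      "type": "object",
      "description": "long table of mean decoding accuracies",
      "required_columns": ["participant", "group", "session", "roi",
                           "condition", "accuracy", "null_lo", "null_hi"]
    },
    "behavior": {
      "type": "object",
      "required_columns": ["participant", "true_group", "n_trials", "accuracy"]
    },
    "classification": {
      "type": "object",
      "required_columns": ["participant", "accuracy", "group"]
    },
    "bias": { "type": ["object", "null"] },
    "group_stats": { "type": "object" }
  }
}
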