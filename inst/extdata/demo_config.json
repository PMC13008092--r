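{
  "data": {
    "synthetic": { "n": 1000, "seed": 42, "design": "demo" }
  },
  "estimation": { "gamma": 0.25, "rule": "and", "use_survey_weights": true },
  "community": { "max_communities": 10, "seed": 7 },
  "nulls": { "n_null": 50, "seed": 11 },
  "ablation": { "top_k": 2, "attribute": "construct" },
  "inference": { "B": 200, "seed": 13, "enabled": true },
  "sweep": { "step": 0.05, "enabled": true }
}
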