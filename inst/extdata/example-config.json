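{
  "seed": 7,
  "items": ["sleep"],
  "min_ema": 10,
  "modes": ["single", "combined"],
  "shared_link": true,
  "grid": {
    "learning_rate": [0.1],
    "n_trees": [20, 100],
    "depth": [3],
    "smote": [false],
    "k": ["all"]
  },
  "study_a": {
    "study_id": "crosscheck",
    "n_subjects": 4,
    "n_days": 40,
    "seed": 41,
    "subject_sd": 0.4,
    "n_cal": 400,
    "links": {
      "sleep": {
        "weights": {"sleep_duration": 0.8, "unlock_duration": -0.5},
        "noise_sd": 0.5,
        "grid": [0, 1, 2, 3],
        "category_prior": [0.08, 0.14, 0.45, 0.33]
      }
    },
    "shift": {"missing_rate": 0.08}
  },
  "study_b": {
    "study_id": "studentlife",
    "n_subjects": 4,
    "n_days": 40,
    "seed": 42,
    "subject_sd": 0.4,
    "n_cal": 400,
    "raw_derived": true,
    "mappings": {"sleep": "studentlife_sleep"},
    "shift": {
      "location": {"location_distance": 4},
      "missing_rate": 0.12,
      "schedule": {"type": "bernoulli", "period": 2.5}
    }
  }
}
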