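{
  "seed": 1,
  "arena": {
    "side_length": 50,
    "grid_cell": 10,
    "wall_height": 35
  },
  "session": {
    "dt": 0.0333333333333333,
    "duration_min": 90
  },
  "behavior": {
    "bout_rate0": 10.5,
    "bout_mean_dur": 4,
    "speed_scale": 14,
    "speed_sdlog": 0.45,
    "habituation_tau": 45,
    "round_factor": 0.85,
    "thigmotaxis_strength": 2,
    "heading_persistence": 0.15,
    "freeze_frac": 0.35,
    "posture_noise": 0.25,
    "body_length": 8
  },
  "pharmacodynamics": {
    "SCH23390":    { "emax": 0.97, "ed50": 0.02, "hill": 1.5, "ka": 0.3, "ke": 0.04 },
    "haloperidol": { "emax": 0.97, "ed50": 0.2,  "hill": 1.5, "ka": 0.3, "ke": 0.04 }
  },
  "design": {
    "n_animals": 48,
    "n_rounds": 4,
    "doses": {
      "SCH23390": [0.005, 0.01, 0.02, 0.05, 0.5],
      "haloperidol": [0.05, 0.1, 0.2, 0.5, 1]
    }
  },
  "metrics": {
    "min_dur": 2,
    "v_thresh": 1,
    "smooth_win": 0.5,
    "merge_gap": 0.2,
    "filter_cap": 80,
    "bin_width_min": 5,
    "toi_min": [10, 60]
  },
  "stats": {
    "control": "saline",
    "sidak_family": "per_row",
    "alpha": 0.05
  }
}
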