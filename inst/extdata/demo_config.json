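{
  "seed": 42,
  "stages": ["flow", "gradient", "dose", "evolution", "summary"],
  "flow": {
    "n_events": 10000,
    "responder_fraction": 0.3,
    "null_log_mean": 1.5,
    "null_log_sd": 0.15,
    "shift": 1,
    "n_bins": 64,
    "bin_range": [0, 5],
    "smooth_window": 500
  },
  "gradient": {
    "drm_center": 3,
    "dsm_center": 8,
    "background_offset": 50,
    "noise_sd": 5
  },
  "dose": {
    "top_conc_uM": 30,
    "dilution": 3,
    "n_points": 12,
    "top": 2000,
    "ec50": 500,
    "hill": 1.5,
    "cv": 0.1,
    "n_reps": 3,
    "sensitivity_nM": 41
  },
  "evolution": {
    "n_tips": 8,
    "branch_length": 0.2,
    "n_neutral": 30,
    "n_conserved": 10,
    "n_covary_pairs": 2,
    "n_codons": 40,
    "kappa": 2,
    "criteria": {
      "mi_lo": 4,
      "cons_lo": -0.5,
      "mi_hi": 8,
      "cons_hi": -0.3,
      "select_fraction": 0.005
    }
  },
  "lines": {
    "WT": {
      "control": "WT",
      "il2_scale": 1,
      "signal_scale": 1,
      "lck_drm_scale": 1,
      "endo_scale": 1
    },
    "T1": {
      "control": "WT",
      "il2_scale": 0.6,
      "signal_scale": 1,
      "lck_drm_scale": 0.35,
      "endo_scale": 0.5
    },
    "T1.TP": {
      "control": "T1",
      "il2_scale": 0.1,
      "signal_scale": 0.5,
      "lck_drm_scale": 0.3,
      "endo_scale": 0.2
    }
  }
}
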