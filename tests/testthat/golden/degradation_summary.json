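{
  "config_hash": "5c206c0b",
  "end_tolerance_fraction": 0.1,
  "end_tolerance_min": 20,
  "per_sample": {
    "Exo1": {
      "proportions": {
        "deg_3to5": 0.43596059113,
        "endo": 0.34698275862,
        "deg_5to3": 0.21705665025
      },
      "n": 3248,
      "n_ambiguous": 0
    },
    "Exo2": {
      "proportions": {
        "deg_3to5": 0.41932457786,
        "endo": 0.34146341463,
        "deg_5to3": 0.2392120075
      },
      "n": 3198,
      "n_ambiguous": 0
    },
    "Exo3": {
      "proportions": {
        "deg_3to5": 0.42848160956,
        "endo": 0.34234517447,
        "deg_5to3": 0.22917321597
      },
      "n": 3181,
      "n_ambiguous": 0
    },
    "MV1": {
      "proportions": {
        "deg_3to5": 0.43424993194,
        "endo": 0.33188129594,
        "deg_5to3": 0.23386877212
      },
      "n": 3673,
      "n_ambiguous": 0
    },
    "MV2": {
      "proportions": {
        "deg_3to5": 0.42807671817,
        "endo": 0.34256792754,
        "deg_5to3": 0.22935535429
      },
      "n": 3754,
      "n_ambiguous": 0
    },
    "MV3": {
      "proportions": {
        "deg_3to5": 0.43240314278,
        "endo": 0.34380926578,
        "deg_5to3": 0.22378759144
      },
      "n": 3691,
      "n_ambiguous": 0
    }
  },
  "overall": {
    "proportions": {
      "deg_3to5": 0.42988671969,
      "endo": 0.3413834659,
      "deg_5to3": 0.22872981441
    },
    "n": 20745,
    "n_ambiguous": 0
  }
}
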