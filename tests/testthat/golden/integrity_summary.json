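{
  "config_hash": "5c206c0b",
  "intact_threshold": 0.9,
  "unit": "read",
  "per_sample": [
    {
      "sample_id": "Exo1",
      "group": "Exo",
      "n": 5000,
      "n_intact": 1752,
      "intact_proportion": 0.3504
    },
    {
      "sample_id": "Exo2",
      "group": "Exo",
      "n": 5000,
      "n_intact": 1802,
      "intact_proportion": 0.3604
    },
    {
      "sample_id": "Exo3",
      "group": "Exo",
      "n": 5000,
      "n_intact": 1819,
      "intact_proportion": 0.3638
    },
    {
      "sample_id": "MV1",
      "group": "MV",
      "n": 5000,
      "n_intact": 1327,
      "intact_proportion": 0.2654
    },
    {
      "sample_id": "MV2",
      "group": "MV",
      "n": 5000,
      "n_intact": 1246,
      "intact_proportion": 0.2492
    },
    {
      "sample_id": "MV3",
      "group": "MV",
      "n": 5000,
      "n_intact": 1309,
      "intact_proportion": 0.2618
    }
  ],
  "per_group": {
    "Exo": {
      "n_samples": 3,
      "mean_intact_proportion": 0.3582
    },
    "MV": {
      "n_samples": 3,
      "mean_intact_proportion": 0.2588
    }
  },
  "overall": {
    "n_reads": 30000,
    "intact_proportion": 0.3085
  },
  "welch_t": {
    "statistic": 15.6592077564,
    "df": 3.8502414705,
    "p_value": 0.00012516190761,
    "method": "Welch t"
  }
}
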