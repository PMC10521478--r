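{
  "config_hash": "5c206c0b",
  "intrinsic": {
    "n_intrinsic": 123,
    "n_union": 161,
    "proportion": 0.76397515528,
    "denominator": "union",
    "table": [
      [123, 123],
      [17, 7]
    ],
    "chi_square": {
      "statistic": 3.801510989,
      "df": 1,
      "p_value": 0.051206354032,
      "method": "chi-square"
    }
  },
  "group_specific": {
    "Exo": {
      "n_transcripts": 28,
      "n_genes": 9
    },
    "MV": {
      "n_transcripts": 27,
      "n_genes": 6
    }
  },
  "n_shared_transcripts": 244,
  "machinery_detected": []
}
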