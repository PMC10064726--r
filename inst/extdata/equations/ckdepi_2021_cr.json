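{
  "schema_version": 1,
  "name": "ckdepi_2021_cr",
  "label": "eGFRcr(AS)",
  "constant": 142,
  "terms": [
    {
      "marker": "scr",
      "knot": {"female": 0.7, "male": 0.9},
      "min_exponent": {"female": -0.241, "male": -0.302},
      "max_exponent": -1.200
    }
  ],
  "age_base": 0.9938,
  "female_factor": 1.012,
  "black_factor": 1.0
}
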