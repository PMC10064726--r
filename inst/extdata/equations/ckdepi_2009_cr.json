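{
  "schema_version": 1,
  "name": "ckdepi_2009_cr",
  "label": "eGFRcr(ASR)",
  "constant": 141,
  "terms": [
    {
      "marker": "scr",
      "knot": {"female": 0.7, "male": 0.9},
      "min_exponent": {"female": -0.329, "male": -0.411},
      "max_exponent": -1.209
    }
  ],
  "age_base": 0.993,
  "female_factor": 1.018,
  "black_factor": 1.159
}
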