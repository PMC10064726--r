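{
  "schema_version": 1,
  "name": "ckdepi_2021_crcys",
  "label": "eGFRcr-cys(AS)",
  "constant": 135,
  "terms": [
    {
      "marker": "scr",
      "knot": {"female": 0.7, "male": 0.9},
      "min_exponent": {"female": -0.219, "male": -0.144},
      "max_exponent": -0.544
    },
    {
      "marker": "scys",
      "knot": 0.8,
      "min_exponent": -0.323,
      "max_exponent": -0.778
    }
  ],
  "age_base": 0.9961,
  "female_factor": 0.963,
  "black_factor": 1.0
}
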