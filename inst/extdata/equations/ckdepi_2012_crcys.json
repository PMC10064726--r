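{
  "schema_version": 1,
  "name": "ckdepi_2012_crcys",
  "label": "eGFRcr-cys(ASR)",
  "constant": 135,
  "terms": [
    {
      "marker": "scr",
      "knot": {"female": 0.7, "male": 0.9},
      "min_exponent": {"female": -0.248, "male": -0.207},
      "max_exponent": -0.601
    },
    {
      "marker": "scys",
      "knot": 0.8,
      "min_exponent": -0.375,
      "max_exponent": -0.711
    }
  ],
  "age_base": 0.995,
  "female_factor": 0.969,
  "black_factor": 1.08
}
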