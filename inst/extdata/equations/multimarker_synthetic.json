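{
  "schema_version": 1,
  "name": "multimarker_synthetic",
  "label": "eGFRmulti (synthetic stand-in)",
  "note": "SYNTHETIC NON-CLINICAL stand-in for a multi-metabolite serum equation (creatinine, cystatin C, myo-inositol, valine). Coefficients are illustrative placeholders exercising the pluggable-equation machinery; they are NOT a published equation and must never be used for patient care. Replace this file with validated coefficients to evaluate a real multimarker equation.",
  "constant": 140,
  "terms": [
    {
      "marker": "scr",
      "knot": {"female": 0.7, "male": 0.9},
      "min_exponent": {"female": -0.22, "male": -0.14},
      "max_exponent": -0.50
    },
    {
      "marker": "scys",
      "knot": 0.8,
      "min_exponent": -0.30,
      "max_exponent": -0.70
    },
    {
      "marker": "myo_inositol",
      "knot": 30.0,
      "min_exponent": -0.05,
      "max_exponent": -0.20
    },
    {
      "marker": "valine",
      "knot": 240.0,
      "min_exponent": 0.10,
      "max_exponent": 0.25
    }
  ],
  "age_base": 0.996,
  "female_factor": 0.96,
  "black_factor": 1.0
}
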