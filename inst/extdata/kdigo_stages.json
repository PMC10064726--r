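{
  "schema_version": 1,
  "note": "KDIGO/KDOQI GFR categories, ml/min/1.73 m2. 'lower' is the inclusive lower bound of each stage; stages ordered from best (G1) to worst (G5) kidney function.",
  "stages": [
    {"stage": "G1",  "lower": 90},
    {"stage": "G2",  "lower": 60},
    {"stage": "G3a", "lower": 45},
    {"stage": "G3b", "lower": 30},
    {"stage": "G4",  "lower": 15},
    {"stage": "G5",  "lower": 0}
  ]
}
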