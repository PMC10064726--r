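{
  "schema_version": 1,
  "note": "Child-Pugh laboratory component scoring. Each component lists the cutpoints separating 1/2/3 points; 'direction' says whether larger values are worse. Boundary values score the middle category (2 points). Centers grading coagulation by prothrombin activity instead of INR can substitute their own component here.",
  "components": {
    "bilirubin": {"unit": "mg/dL", "direction": "higher_worse", "cut_low": 2.0, "cut_high": 3.0},
    "albumin":   {"unit": "g/dL",  "direction": "lower_worse",  "cut_low": 2.8, "cut_high": 3.5},
    "inr":       {"unit": "",      "direction": "higher_worse", "cut_low": 1.7, "cut_high": 2.3}
  }
}
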