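# Default risk-category binning for vitals (C1-C4) and Low/Normal/High
# reference ranges for labs. Vital boundaries are age-stratified; `bands` are
# matched by `max_age` (years, exclusive upper bound) in order. For vitals
# marked `descending: true` lower values are worse, so the four intervals map
# to C4..C1 instead of C1..C4. These defaults are editable configuration, not
# clinical reference values.
vitals:
  "Heart rate":
    descending: false
    bands:
      - {max_age: 1,    bounds: [132, 146, 160]}
      - {max_age: 5,    bounds: [126, 140, 154]}
      - {max_age: 12,   bounds: [122, 134, 146]}
      - {max_age: 18,   bounds: [118, 130, 142]}
      - {max_age: .inf, bounds: [114, 126, 138]}
  "Respiratory rate":
    descending: false
    bands:
      - {max_age: 1,    bounds: [36, 41, 46]}
      - {max_age: 5,    bounds: [34, 39, 44]}
      - {max_age: 12,   bounds: [33, 38, 42]}
      - {max_age: 18,   bounds: [32, 37, 41]}
      - {max_age: .inf, bounds: [31, 36, 40]}
  "Temperature":
    descending: false
    bands:
      - {max_age: .inf, bounds: [37.3, 37.7, 38.1]}
  "Systolic blood pressure":
    descending: true
    bands:
      - {max_age: 1,    bounds: [68, 78, 88]}
      - {max_age: 5,    bounds: [70, 80, 90]}
      - {max_age: 12,   bounds: [72, 82, 92]}
      - {max_age: 18,   bounds: [74, 84, 94]}
      - {max_age: .inf, bounds: [76, 86, 96]}
  "Oxygen saturation":
    descending: true
    bands:
      - {max_age: .inf, bounds: [93.9, 95.1, 96.3]}
labs:
  "Sodium":                 {low: 135, high: 145}
  "Potassium":              {low: 3.5, high: 5.0}
  "Glucose":                {low: 70,  high: 140}
  "Creatinine":             {low: 0.3, high: 1.0}
  "Bicarbonate":            {low: 20,  high: 28}
  "White blood cell count": {low: 5,   high: 14.5}
  "Hematocrit":             {low: 34,  high: 44}
  "Hemoglobin":             {low: 11,  high: 15}
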