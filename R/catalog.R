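# Synthetic clinical-element catalog. Mirrors the usual pediatric floor chart:
# five scalar vitals, eight labs with Low/Normal/High reference ranges, two
# integer acuity scores, and a set of nursing-assessment attributes whose
# values are drawn from fixed vocabularies ordered from normal to severe.
# `dir` is the direction a deteriorating patient drifts (+1 up, -1 down).

vital_catalog <- function() {
  tibble::tribble(
    ~attribute,                ~mean, ~sd,  ~dir, ~unit,   ~digits,
    "Heart rate",              110,   15,   1,    "bpm",   0,
    "Respiratory rate",        28,    6,    1,    "rpm",   0,
    "Temperature",             37.0,  0.4,  1,    "degC",  1,
    "Systolic blood pressure", 100,   12,  -1,    "mmHg",  0,
    "Oxygen saturation",       97.5,  1.5, -1,    "%",     1
  )
}

lab_catalog <- function() {
  out <- tibble::tribble(
    ~attribute,               ~low, ~high, ~dir, ~unit,
    "Sodium",                 135,  145,  -1,    "mmol/L",
    "Potassium",              3.5,  5.0,   1,    "mmol/L",
    "Glucose",                70,   140,   1,    "mg/dL",
    "Creatinine",             0.3,  1.0,   1,    "mg/dL",
    "Bicarbonate",            20,   28,   -1,    "mmol/L",
    "White blood cell count", 5,    14.5,  1,    "10^3/uL",
    "Hematocrit",             34,   44,   -1,    "%",
    "Hemoglobin",             11,   15,   -1,    "g/dL"
  )
  out$center <- (out$low + out$high) / 2
  out$sd <- (out$high - out$low) / 4
  out
}

acuity_catalog <- function() {
  tibble::tribble(
    ~attribute,         ~min, ~max, ~base_mean, ~base_sd, ~gain,
    "PEWS total score", 0,    9,    1.0,        1.0,      1.5,
    "Acuity level",     1,    5,    2.0,        0.8,      1.0
  )
}

assessment_catalog <- function() {
  list(
    "Work of breathing"      = c("normal", "mild", "moderate", "severe"),
    "Cough"                  = c("none", "dry", "productive"),
    "Level of consciousness" = c("alert", "drowsy", "lethargic", "unresponsive"),
    "Mobility"               = c("1", "2", "3", "4"),
    "Perfusion cap refill"   = c("brisk", "sluggish", "prolonged"),
    "Respiratory status"     = c("stable", "compromised")
  )
}

# Intervention event vocabulary. `cde` marks types that qualify as critical
# deterioration events (positive-pressure ventilation, vasopressors, fluid
# resuscitation, emergent procedures); ICU-only infusions flag a transfer as
# unplanned without qualifying as a CDE.
intervention_catalog <- function() {
  tibble::tribble(
    ~kind,         ~category,      ~attributes,                                   ~cde, ~weight,
    "respiratory", "resp_support", list(c("BiPAP initiation", "CPAP initiation",
                                          "invasive ventilation initiation")),    TRUE,  0.40,
    "vasopressor", "med",          list(c("epinephrine infusion",
                                          "norepinephrine infusion",
                                          "dopamine infusion")),                  TRUE,  0.15,
    "fluid_bolus", "med",          list(c("NS bolus", "LR bolus")),               TRUE,  0.20,
    "emergent",    "med",          list(c("CPR", "rapid response activation")),   TRUE,  0.05,
    "icu_med",     "med",          list(c("milrinone infusion",
                                          "vasopressin infusion")),               FALSE, 0.20
  )
}

diagnosis_groups <- function() {
  c("respiratory", "cardiac", "neurologic", "oncologic",
    "gastrointestinal", "infectious", "other")
}
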