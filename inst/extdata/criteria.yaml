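# Default definitions of the five unplanned-transfer criteria. Each criterion
# matches events of one category whose attribute is in `attributes`, inside
# the closed `window` (hours around the transfer); `min_value` (optional)
# is a lower bound on the event's numeric value.
respiratory_support:
  category: resp_support
  attributes: [CPAP initiation, BiPAP initiation, invasive ventilation initiation]
  window: [-2, 12]
vasopressor:
  category: med
  attributes: [epinephrine infusion, norepinephrine infusion, dopamine infusion]
  window: [-2, 12]
fluid_bolus:
  category: med
  attributes: [NS bolus, LR bolus]
  min_value: 20     # mL/kg
  window: [-2, 12]
emergent_procedure:
  category: med
  attributes: [CPR, rapid response activation]
  window: [-2, 12]
icu_medication:
  category: med
  attributes: [milrinone infusion, vasopressin infusion]
  window: [-2, 12]
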