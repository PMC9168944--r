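{
  "profile_id": "default_cohort",
  "size": 24,
  "mode": "exact-count",
  "seed": 20240101,
  "timepoints": [
    {
      "label": "3-month",
      "index": 1
    },
    {
      "label": "12-month",
      "index": 2
    }
  ],
  "improvement_drift": 0.25,
  "default_prevalence": 0.5,
  "default_severity": 0.3,
  "prevalence": {
    "fas:fatigue": 0.833333333333333,
    "sis_plus:sleep": 0.75,
    "eq5d3l:vas": 0.708333333333333,
    "sis3:strength": 0.708333333333333,
    "hads:anxiety": 0.666666666666667
  }
}
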