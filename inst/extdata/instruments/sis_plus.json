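{
  "instrument_id": "sis_plus",
  "name": "SIS additional questions (sensory, sleep, pain, continence, sexuality)",
  "orientation": "higher-raw-is-better",
  "scoring_rule": "mean-rescale",
  "domains": [
    {
      "domain_id": "sensory",
      "name": "Sensory disturbance"
    },
    {
      "domain_id": "sleep",
      "name": "Sleep disturbance"
    },
    {
      "domain_id": "pain",
      "name": "Pain"
    },
    {
      "domain_id": "continence",
      "name": "Continence"
    },
    {
      "domain_id": "sexuality",
      "name": "Sexual function"
    }
  ],
  "items": [
    {
      "item_id": "sisp_sensory_01",
      "prompt": "Item sisp_sensory_01 (placeholder prompt)",
      "domain_id": "sensory",
      "levels": [
        {
          "code": 1,
          "label": "worst"
        },
        {
          "code": 2,
          "label": "poor"
        },
        {
          "code": 3,
          "label": "fair"
        },
        {
          "code": 4,
          "label": "good"
        },
        {
          "code": 5,
          "label": "best / no problem"
        }
      ]
    },
    {
      "item_id": "sisp_sensory_02",
      "prompt": "Item sisp_sensory_02 (placeholder prompt)",
      "domain_id": "sensory",
      "levels": [
        {
          "code": 1,
          "label": "worst"
        },
        {
          "code": 2,
          "label": "poor"
        },
        {
          "code": 3,
          "label": "fair"
        },
        {
          "code": 4,
          "label": "good"
        },
        {
          "code": 5,
          "label": "best / no problem"
        }
      ]
    },
    {
      "item_id": "sisp_sleep_01",
      "prompt": "Item sisp_sleep_01 (placeholder prompt)",
      "domain_id": "sleep",
      "levels": [
        {
          "code": 1,
          "label": "worst"
        },
        {
          "code": 2,
          "label": "poor"
        },
        {
          "code": 3,
          "label": "fair"
        },
        {
          "code": 4,
          "label": "good"
        },
        {
          "code": 5,
          "label": "best / no problem"
        }
      ]
    },
    {
      "item_id": "sisp_sleep_02",
      "prompt": "Item sisp_sleep_02 (placeholder prompt)",
      "domain_id": "sleep",
      "levels": [
        {
          "code": 1,
          "label": "worst"
        },
        {
          "code": 2,
          "label": "poor"
        },
        {
          "code": 3,
          "label": "fair"
        },
        {
          "code": 4,
          "label": "good"
        },
        {
          "code": 5,
          "label": "best / no problem"
        }
      ]
    },
    {
      "item_id": "sisp_pain_01",
      "prompt": "Item sisp_pain_01 (placeholder prompt)",
      "domain_id": "pain",
      "levels": [
        {
          "code": 1,
          "label": "worst"
        },
        {
          "code": 2,
          "label": "poor"
        },
        {
          "code": 3,
          "label": "fair"
        },
        {
          "code": 4,
          "label": "good"
        },
        {
          "code": 5,
          "label": "best / no problem"
        }
      ]
    },
    {
      "item_id": "sisp_continence_01",
      "prompt": "Item sisp_continence_01 (placeholder prompt)",
      "domain_id": "continence",
      "levels": [
        {
          "code": 1,
          "label": "worst"
        },
        {
          "code": 2,
          "label": "poor"
        },
        {
          "code": 3,
          "label": "fair"
        },
        {
          "code": 4,
          "label": "good"
        },
        {
          "code": 5,
          "label": "best / no problem"
        }
      ]
    },
    {
      "item_id": "sisp_continence_02",
      "prompt": "Item sisp_continence_02 (placeholder prompt)",
      "domain_id": "continence",
      "levels": [
        {
          "code": 1,
          "label": "worst"
        },
        {
          "code": 2,
          "label": "poor"
        },
        {
          "code": 3,
          "label": "fair"
        },
        {
          "code": 4,
          "label": "good"
        },
        {
          "code": 5,
          "label": "best / no problem"
        }
      ]
    },
    {
      "item_id": "sisp_sexuality_01",
      "prompt": "Item sisp_sexuality_01 (placeholder prompt)",
      "domain_id": "sexuality",
      "levels": [
        {
          "code": 1,
          "label": "worst"
        },
        {
          "code": 2,
          "label": "poor"
        },
        {
          "code": 3,
          "label": "fair"
        },
        {
          "code": 4,
          "label": "good"
        },
        {
          "code": 5,
          "label": "best / no problem"
        }
      ]
    }
  ]
}
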