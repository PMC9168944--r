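{
  "instrument_id": "eat10",
  "name": "Eating Assessment Tool",
  "orientation": "higher-raw-is-worse",
  "scoring_rule": "sum-rescale",
  "domains": [
    {
      "domain_id": "swallowing",
      "name": "Swallowing"
    }
  ],
  "items": [
    {
      "item_id": "eat_01",
      "prompt": "Item eat_01 (placeholder prompt)",
      "domain_id": "swallowing",
      "levels": [
        {
          "code": 0,
          "label": "no problem"
        },
        {
          "code": 1,
          "label": "mild"
        },
        {
          "code": 2,
          "label": "moderate"
        },
        {
          "code": 3,
          "label": "severe"
        },
        {
          "code": 4,
          "label": "serious problem"
        }
      ]
    },
    {
      "item_id": "eat_02",
      "prompt": "Item eat_02 (placeholder prompt)",
      "domain_id": "swallowing",
      "levels": [
        {
          "code": 0,
          "label": "no problem"
        },
        {
          "code": 1,
          "label": "mild"
        },
        {
          "code": 2,
          "label": "moderate"
        },
        {
          "code": 3,
          "label": "severe"
        },
        {
          "code": 4,
          "label": "serious problem"
        }
      ]
    },
    {
      "item_id": "eat_03",
      "prompt": "Item eat_03 (placeholder prompt)",
      "domain_id": "swallowing",
      "levels": [
        {
          "code": 0,
          "label": "no problem"
        },
        {
          "code": 1,
          "label": "mild"
        },
        {
          "code": 2,
          "label": "moderate"
        },
        {
          "code": 3,
          "label": "severe"
        },
        {
          "code": 4,
          "label": "serious problem"
        }
      ]
    },
    {
      "item_id": "eat_04",
      "prompt": "Item eat_04 (placeholder prompt)",
      "domain_id": "swallowing",
      "levels": [
        {
          "code": 0,
          "label": "no problem"
        },
        {
          "code": 1,
          "label": "mild"
        },
        {
          "code": 2,
          "label": "moderate"
        },
        {
          "code": 3,
          "label": "severe"
        },
        {
          "code": 4,
          "label": "serious problem"
        }
      ]
    },
    {
      "item_id": "eat_05",
      "prompt": "Item eat_05 (placeholder prompt)",
      "domain_id": "swallowing",
      "levels": [
        {
          "code": 0,
          "label": "no problem"
        },
        {
          "code": 1,
          "label": "mild"
        },
        {
          "code": 2,
          "label": "moderate"
        },
        {
          "code": 3,
          "label": "severe"
        },
        {
          "code": 4,
          "label": "serious problem"
        }
      ]
    },
    {
      "item_id": "eat_06",
      "prompt": "Item eat_06 (placeholder prompt)",
      "domain_id": "swallowing",
      "levels": [
        {
          "code": 0,
          "label": "no problem"
        },
        {
          "code": 1,
          "label": "mild"
        },
        {
          "code": 2,
          "label": "moderate"
        },
        {
          "code": 3,
          "label": "severe"
        },
        {
          "code": 4,
          "label": "serious problem"
        }
      ]
    },
    {
      "item_id": "eat_07",
      "prompt": "Item eat_07 (placeholder prompt)",
      "domain_id": "swallowing",
      "levels": [
        {
          "code": 0,
          "label": "no problem"
        },
        {
          "code": 1,
          "label": "mild"
        },
        {
          "code": 2,
          "label": "moderate"
        },
        {
          "code": 3,
          "label": "severe"
        },
        {
          "code": 4,
          "label": "serious problem"
        }
      ]
    },
    {
      "item_id": "eat_08",
      "prompt": "Item eat_08 (placeholder prompt)",
      "domain_id": "swallowing",
      "levels": [
        {
          "code": 0,
          "label": "no problem"
        },
        {
          "code": 1,
          "label": "mild"
        },
        {
          "code": 2,
          "label": "moderate"
        },
        {
          "code": 3,
          "label": "severe"
        },
        {
          "code": 4,
          "label": "serious problem"
        }
      ]
    },
    {
      "item_id": "eat_09",
      "prompt": "Item eat_09 (placeholder prompt)",
      "domain_id": "swallowing",
      "levels": [
        {
          "code": 0,
          "label": "no problem"
        },
        {
          "code": 1,
          "label": "mild"
        },
        {
          "code": 2,
          "label": "moderate"
        },
        {
          "code": 3,
          "label": "severe"
        },
        {
          "code": 4,
          "label": "serious problem"
        }
      ]
    },
    {
      "item_id": "eat_10",
      "prompt": "Item eat_10 (placeholder prompt)",
      "domain_id": "swallowing",
      "levels": [
        {
          "code": 0,
          "label": "no problem"
        },
        {
          "code": 1,
          "label": "mild"
        },
        {
          "code": 2,
          "label": "moderate"
        },
        {
          "code": 3,
          "label": "severe"
        },
        {
          "code": 4,
          "label": "serious problem"
        }
      ]
    }
  ]
}
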