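{
  "instrument_id": "fas",
  "name": "Fatigue Assessment Scale",
  "orientation": "higher-raw-is-worse",
  "scoring_rule": "sum-rescale",
  "domains": [
    {
      "domain_id": "fatigue",
      "name": "Fatigue"
    }
  ],
  "items": [
    {
      "item_id": "fas_01",
      "prompt": "Item fas_01 (placeholder prompt)",
      "domain_id": "fatigue",
      "levels": [
        {
          "code": 1,
          "label": "never"
        },
        {
          "code": 2,
          "label": "sometimes"
        },
        {
          "code": 3,
          "label": "regularly"
        },
        {
          "code": 4,
          "label": "often"
        },
        {
          "code": 5,
          "label": "always"
        }
      ]
    },
    {
      "item_id": "fas_02",
      "prompt": "Item fas_02 (placeholder prompt)",
      "domain_id": "fatigue",
      "levels": [
        {
          "code": 1,
          "label": "never"
        },
        {
          "code": 2,
          "label": "sometimes"
        },
        {
          "code": 3,
          "label": "regularly"
        },
        {
          "code": 4,
          "label": "often"
        },
        {
          "code": 5,
          "label": "always"
        }
      ]
    },
    {
      "item_id": "fas_03",
      "prompt": "Item fas_03 (placeholder prompt)",
      "domain_id": "fatigue",
      "levels": [
        {
          "code": 1,
          "label": "never"
        },
        {
          "code": 2,
          "label": "sometimes"
        },
        {
          "code": 3,
          "label": "regularly"
        },
        {
          "code": 4,
          "label": "often"
        },
        {
          "code": 5,
          "label": "always"
        }
      ]
    },
    {
      "item_id": "fas_04",
      "prompt": "Item fas_04 (placeholder prompt)",
      "domain_id": "fatigue",
      "levels": [
        {
          "code": 1,
          "label": "never"
        },
        {
          "code": 2,
          "label": "sometimes"
        },
        {
          "code": 3,
          "label": "regularly"
        },
        {
          "code": 4,
          "label": "often"
        },
        {
          "code": 5,
          "label": "always"
        }
      ]
    },
    {
      "item_id": "fas_05",
      "prompt": "Item fas_05 (placeholder prompt)",
      "domain_id": "fatigue",
      "levels": [
        {
          "code": 1,
          "label": "never"
        },
        {
          "code": 2,
          "label": "sometimes"
        },
        {
          "code": 3,
          "label": "regularly"
        },
        {
          "code": 4,
          "label": "often"
        },
        {
          "code": 5,
          "label": "always"
        }
      ]
    },
    {
      "item_id": "fas_06",
      "prompt": "Item fas_06 (placeholder prompt)",
      "domain_id": "fatigue",
      "levels": [
        {
          "code": 1,
          "label": "never"
        },
        {
          "code": 2,
          "label": "sometimes"
        },
        {
          "code": 3,
          "label": "regularly"
        },
        {
          "code": 4,
          "label": "often"
        },
        {
          "code": 5,
          "label": "always"
        }
      ]
    },
    {
      "item_id": "fas_07",
      "prompt": "Item fas_07 (placeholder prompt)",
      "domain_id": "fatigue",
      "levels": [
        {
          "code": 1,
          "label": "never"
        },
        {
          "code": 2,
          "label": "sometimes"
        },
        {
          "code": 3,
          "label": "regularly"
        },
        {
          "code": 4,
          "label": "often"
        },
        {
          "code": 5,
          "label": "always"
        }
      ]
    },
    {
      "item_id": "fas_08",
      "prompt": "Item fas_08 (placeholder prompt)",
      "domain_id": "fatigue",
      "levels": [
        {
          "code": 1,
          "label": "never"
        },
        {
          "code": 2,
          "label": "sometimes"
        },
        {
          "code": 3,
          "label": "regularly"
        },
        {
          "code": 4,
          "label": "often"
        },
        {
          "code": 5,
          "label": "always"
        }
      ]
    },
    {
      "item_id": "fas_09",
      "prompt": "Item fas_09 (placeholder prompt)",
      "domain_id": "fatigue",
      "levels": [
        {
          "code": 1,
          "label": "never"
        },
        {
          "code": 2,
          "label": "sometimes"
        },
        {
          "code": 3,
          "label": "regularly"
        },
        {
          "code": 4,
          "label": "often"
        },
        {
          "code": 5,
          "label": "always"
        }
      ]
    },
    {
      "item_id": "fas_10",
      "prompt": "Item fas_10 (placeholder prompt)",
      "domain_id": "fatigue",
      "levels": [
        {
          "code": 1,
          "label": "never"
        },
        {
          "code": 2,
          "label": "sometimes"
        },
        {
          "code": 3,
          "label": "regularly"
        },
        {
          "code": 4,
          "label": "often"
        },
        {
          "code": 5,
          "label": "always"
        }
      ]
    }
  ]
}
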