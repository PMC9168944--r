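{
  "instrument_id": "hads",
  "name": "Hospital Anxiety and Depression Scale",
  "orientation": "higher-raw-is-worse",
  "scoring_rule": "sum-rescale",
  "domains": [
    {
      "domain_id": "anxiety",
      "name": "Anxiety"
    },
    {
      "domain_id": "depression",
      "name": "Depression"
    }
  ],
  "items": [
    {
      "item_id": "hads_anx_01",
      "prompt": "Item hads_anx_01 (placeholder prompt)",
      "domain_id": "anxiety",
      "levels": [
        {
          "code": 0,
          "label": "not at all"
        },
        {
          "code": 1,
          "label": "occasionally"
        },
        {
          "code": 2,
          "label": "often"
        },
        {
          "code": 3,
          "label": "most of the time"
        }
      ]
    },
    {
      "item_id": "hads_anx_02",
      "prompt": "Item hads_anx_02 (placeholder prompt)",
      "domain_id": "anxiety",
      "levels": [
        {
          "code": 0,
          "label": "not at all"
        },
        {
          "code": 1,
          "label": "occasionally"
        },
        {
          "code": 2,
          "label": "often"
        },
        {
          "code": 3,
          "label": "most of the time"
        }
      ]
    },
    {
      "item_id": "hads_anx_03",
      "prompt": "Item hads_anx_03 (placeholder prompt)",
      "domain_id": "anxiety",
      "levels": [
        {
          "code": 0,
          "label": "not at all"
        },
        {
          "code": 1,
          "label": "occasionally"
        },
        {
          "code": 2,
          "label": "often"
        },
        {
          "code": 3,
          "label": "most of the time"
        }
      ]
    },
    {
      "item_id": "hads_anx_04",
      "prompt": "Item hads_anx_04 (placeholder prompt)",
      "domain_id": "anxiety",
      "levels": [
        {
          "code": 0,
          "label": "not at all"
        },
        {
          "code": 1,
          "label": "occasionally"
        },
        {
          "code": 2,
          "label": "often"
        },
        {
          "code": 3,
          "label": "most of the time"
        }
      ]
    },
    {
      "item_id": "hads_anx_05",
      "prompt": "Item hads_anx_05 (placeholder prompt)",
      "domain_id": "anxiety",
      "levels": [
        {
          "code": 0,
          "label": "not at all"
        },
        {
          "code": 1,
          "label": "occasionally"
        },
        {
          "code": 2,
          "label": "often"
        },
        {
          "code": 3,
          "label": "most of the time"
        }
      ]
    },
    {
      "item_id": "hads_anx_06",
      "prompt": "Item hads_anx_06 (placeholder prompt)",
      "domain_id": "anxiety",
      "levels": [
        {
          "code": 0,
          "label": "not at all"
        },
        {
          "code": 1,
          "label": "occasionally"
        },
        {
          "code": 2,
          "label": "often"
        },
        {
          "code": 3,
          "label": "most of the time"
        }
      ]
    },
    {
      "item_id": "hads_anx_07",
      "prompt": "Item hads_anx_07 (placeholder prompt)",
      "domain_id": "anxiety",
      "levels": [
        {
          "code": 0,
          "label": "not at all"
        },
        {
          "code": 1,
          "label": "occasionally"
        },
        {
          "code": 2,
          "label": "often"
        },
        {
          "code": 3,
          "label": "most of the time"
        }
      ]
    },
    {
      "item_id": "hads_dep_01",
      "prompt": "Item hads_dep_01 (placeholder prompt)",
      "domain_id": "depression",
      "levels": [
        {
          "code": 0,
          "label": "not at all"
        },
        {
          "code": 1,
          "label": "occasionally"
        },
        {
          "code": 2,
          "label": "often"
        },
        {
          "code": 3,
          "label": "most of the time"
        }
      ]
    },
    {
      "item_id": "hads_dep_02",
      "prompt": "Item hads_dep_02 (placeholder prompt)",
      "domain_id": "depression",
      "levels": [
        {
          "code": 0,
          "label": "not at all"
        },
        {
          "code": 1,
          "label": "occasionally"
        },
        {
          "code": 2,
          "label": "often"
        },
        {
          "code": 3,
          "label": "most of the time"
        }
      ]
    },
    {
      "item_id": "hads_dep_03",
      "prompt": "Item hads_dep_03 (placeholder prompt)",
      "domain_id": "depression",
      "levels": [
        {
          "code": 0,
          "label": "not at all"
        },
        {
          "code": 1,
          "label": "occasionally"
        },
        {
          "code": 2,
          "label": "often"
        },
        {
          "code": 3,
          "label": "most of the time"
        }
      ]
    },
    {
      "item_id": "hads_dep_04",
      "prompt": "Item hads_dep_04 (placeholder prompt)",
      "domain_id": "depression",
      "levels": [
        {
          "code": 0,
          "label": "not at all"
        },
        {
          "code": 1,
          "label": "occasionally"
        },
        {
          "code": 2,
          "label": "often"
        },
        {
          "code": 3,
          "label": "most of the time"
        }
      ]
    },
    {
      "item_id": "hads_dep_05",
      "prompt": "Item hads_dep_05 (placeholder prompt)",
      "domain_id": "depression",
      "levels": [
        {
          "code": 0,
          "label": "not at all"
        },
        {
          "code": 1,
          "label": "occasionally"
        },
        {
          "code": 2,
          "label": "often"
        },
        {
          "code": 3,
          "label": "most of the time"
        }
      ]
    },
    {
      "item_id": "hads_dep_06",
      "prompt": "Item hads_dep_06 (placeholder prompt)",
      "domain_id": "depression",
      "levels": [
        {
          "code": 0,
          "label": "not at all"
        },
        {
          "code": 1,
          "label": "occasionally"
        },
        {
          "code": 2,
          "label": "often"
        },
        {
          "code": 3,
          "label": "most of the time"
        }
      ]
    },
    {
      "item_id": "hads_dep_07",
      "prompt": "Item hads_dep_07 (placeholder prompt)",
      "domain_id": "depression",
      "levels": [
        {
          "code": 0,
          "label": "not at all"
        },
        {
          "code": 1,
          "label": "occasionally"
        },
        {
          "code": 2,
          "label": "often"
        },
        {
          "code": 3,
          "label": "most of the time"
        }
      ]
    }
  ]
}
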