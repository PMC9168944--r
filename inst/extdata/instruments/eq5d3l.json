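{
  "instrument_id": "eq5d3l",
  "name": "EuroQoL 5-dimension 3-level + VAS",
  "orientation": "higher-raw-is-worse",
  "scoring_rule": "per-dimension-rescale",
  "domains": [
    {
      "domain_id": "mobility",
      "name": "Mobility"
    },
    {
      "domain_id": "selfcare",
      "name": "Self-care"
    },
    {
      "domain_id": "usual",
      "name": "Usual activities"
    },
    {
      "domain_id": "pain_discomfort",
      "name": "Pain / discomfort"
    },
    {
      "domain_id": "anxiety_depression",
      "name": "Anxiety / depression"
    },
    {
      "domain_id": "vas",
      "name": "Health rating (VAS)",
      "scoring_rule": "passthrough-0-100"
    }
  ],
  "items": [
    {
      "item_id": "eq_mobility",
      "prompt": "Item eq_mobility (placeholder prompt)",
      "domain_id": "mobility",
      "levels": [
        {
          "code": 1,
          "label": "no problems"
        },
        {
          "code": 2,
          "label": "some problems"
        },
        {
          "code": 3,
          "label": "extreme problems"
        }
      ]
    },
    {
      "item_id": "eq_selfcare",
      "prompt": "Item eq_selfcare (placeholder prompt)",
      "domain_id": "selfcare",
      "levels": [
        {
          "code": 1,
          "label": "no problems"
        },
        {
          "code": 2,
          "label": "some problems"
        },
        {
          "code": 3,
          "label": "extreme problems"
        }
      ]
    },
    {
      "item_id": "eq_usual",
      "prompt": "Item eq_usual (placeholder prompt)",
      "domain_id": "usual",
      "levels": [
        {
          "code": 1,
          "label": "no problems"
        },
        {
          "code": 2,
          "label": "some problems"
        },
        {
          "code": 3,
          "label": "extreme problems"
        }
      ]
    },
    {
      "item_id": "eq_pain_discomfort",
      "prompt": "Item eq_pain_discomfort (placeholder prompt)",
      "domain_id": "pain_discomfort",
      "levels": [
        {
          "code": 1,
          "label": "no problems"
        },
        {
          "code": 2,
          "label": "some problems"
        },
        {
          "code": 3,
          "label": "extreme problems"
        }
      ]
    },
    {
      "item_id": "eq_anxiety_depression",
      "prompt": "Item eq_anxiety_depression (placeholder prompt)",
      "domain_id": "anxiety_depression",
      "levels": [
        {
          "code": 1,
          "label": "no problems"
        },
        {
          "code": 2,
          "label": "some problems"
        },
        {
          "code": 3,
          "label": "extreme problems"
        }
      ]
    },
    {
      "item_id": "eq_vas",
      "prompt": "Your health today, 0 (worst) to 100 (best)",
      "domain_id": "vas",
      "levels_range": [0, 100],
      "orientation": "higher-raw-is-better"
    }
  ]
}
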