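{
  "instrument_id": "smrsq",
  "name": "Simplified modified Rankin Scale questionnaire",
  "orientation": "higher-raw-is-worse",
  "scoring_rule": "grade-rescale",
  "domains": [
    {
      "domain_id": "grade",
      "name": "Global disability grade",
      "grade_order": ["smrsq_care", "smrsq_badl", "smrsq_iadl", "smrsq_usual", "smrsq_symptom"]
    }
  ],
  "items": [
    {
      "item_id": "smrsq_care",
      "prompt": "Do you require constant care? (yes -> grade 5)",
      "domain_id": "grade",
      "levels": [
        {
          "code": 0,
          "label": "no"
        },
        {
          "code": 1,
          "label": "yes"
        }
      ]
    },
    {
      "item_id": "smrsq_badl",
      "prompt": "Is assistance essential for eating, toileting, hygiene or walking? (yes -> grade 4)",
      "domain_id": "grade",
      "levels": [
        {
          "code": 0,
          "label": "no"
        },
        {
          "code": 1,
          "label": "yes"
        }
      ]
    },
    {
      "item_id": "smrsq_iadl",
      "prompt": "Is assistance essential for meals, chores, finances, shopping or local travel? (yes -> grade 3)",
      "domain_id": "grade",
      "levels": [
        {
          "code": 0,
          "label": "no"
        },
        {
          "code": 1,
          "label": "yes"
        }
      ]
    },
    {
      "item_id": "smrsq_usual",
      "prompt": "Has your condition changed your ability to work or to take part in previous activities? (yes -> grade 2)",
      "domain_id": "grade",
      "levels": [
        {
          "code": 0,
          "label": "no"
        },
        {
          "code": 1,
          "label": "yes"
        }
      ]
    },
    {
      "item_id": "smrsq_symptom",
      "prompt": "Do you have symptoms that bother you? (yes -> grade 1, no -> grade 0)",
      "domain_id": "grade",
      "levels": [
        {
          "code": 0,
          "label": "no"
        },
        {
          "code": 1,
          "label": "yes"
        }
      ]
    }
  ]
}
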