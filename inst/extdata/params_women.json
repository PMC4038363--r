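{
  "sex": "female",
  "attributable_risk": 0.89,
  "variables": [
    {
      "name": "SKINCOLOUR",
      "type": "categorical",
      "levels": ["olive", "medium", "fair"],
      "reference": "olive",
      "odds_ratios": {
        "olive": 1,
        "medium": 2.94,
        "fair": 4.5
      }
    },
    {
      "name": "MOLES_RARM",
      "type": "categorical",
      "levels": ["0", "1", "2", "3+"],
      "reference": "0",
      "odds_ratios": {
        "0": 1,
        "1": 1.34,
        "2": 2.59,
        "3+": 4.28
      }
    },
    {
      "name": "FAMHXMOLES",
      "type": "categorical",
      "levels": ["don't know", "no", "yes"],
      "reference": "don't know",
      "odds_ratios": {
        "don't know": 1,
        "no": 1.09,
        "yes": 2.62
      }
    },
    {
      "name": "NMSC",
      "type": "categorical",
      "levels": ["no", "yes"],
      "reference": "no",
      "odds_ratios": {
        "no": 1,
        "yes": 3.75
      }
    }
  ]
}
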