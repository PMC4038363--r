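{
  "sex": "male",
  "attributable_risk": 0.85,
  "variables": [
    {
      "name": "AGE",
      "type": "categorical",
      "levels": ["<=50", ">50"],
      "reference": "<=50",
      "odds_ratios": {
        "<=50": 1,
        ">50": 2.59
      }
    },
    {
      "name": "OCC18",
      "type": "categorical",
      "levels": ["indoor", "indoor and outdoor", "outdoor"],
      "reference": "indoor",
      "odds_ratios": {
        "indoor": 1,
        "indoor and outdoor": 1.55,
        "outdoor": 1.94
      }
    },
    {
      "name": "MOLES_RARM",
      "type": "count",
      "per_unit_odds_ratio": 1.15
    },
    {
      "name": "BIRTHPLACE",
      "type": "categorical",
      "levels": ["outside NZ", "in NZ"],
      "reference": "outside NZ",
      "odds_ratios": {
        "outside NZ": 1,
        "in NZ": 2.21
      }
    },
    {
      "name": "NMSC",
      "type": "categorical",
      "levels": ["no", "yes"],
      "reference": "no",
      "odds_ratios": {
        "no": 1,
        "yes": 3.1
      }
    }
  ]
}
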