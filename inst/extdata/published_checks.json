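{
  "comment": "Published reference values the reproduce command recomputes from the packaged fixtures, with their comparison tolerances.",
  "chi_squares": {
    "tolerance_abs": 0.005,
    "targets": [
      {"sex": "female", "variable": "AGE", "expected": 3.22},
      {"sex": "male", "variable": "AGE", "expected": 18.98},
      {"sex": "female", "variable": "SKINCOLOUR", "expected": 18.50},
      {"sex": "male", "variable": "NMSC", "expected": 10.41}
    ]
  },
  "relative_risks": {
    "tolerance_rel": 0.005,
    "targets": [
      {"id": "female_high", "sex": "female", "expected": 189.38,
       "profile": {"SKINCOLOUR": "fair", "MOLES_RARM": "3+",
                   "FAMHXMOLES": "yes", "NMSC": "yes"}},
      {"id": "female_medium", "sex": "female", "expected": 12.66,
       "profile": {"SKINCOLOUR": "fair", "MOLES_RARM": "2",
                   "FAMHXMOLES": "no", "NMSC": "no"}},
      {"id": "male_medium_over50", "sex": "male", "expected": 17.71,
       "profile": {"AGE": ">50", "OCC18": "indoor", "MOLES_RARM": 0,
                   "BIRTHPLACE": "in NZ", "NMSC": "yes"}}
    ]
  },
  "absolute_risks": {
    "tolerance": "max(0.1 percentage point, 2% relative)",
    "tolerance_pp": 0.1,
    "tolerance_rel": 0.02,
    "targets": [
      {"id": "female_high_20_central", "sex": "female", "region": "Central",
       "age": 20, "rr": 189.38, "ar": 0.89, "expected_pct": 0.89},
      {"id": "female_high_80_midland", "sex": "female", "region": "Midland",
       "age": 80, "rr": 189.38, "ar": 0.89, "expected_pct": 14.52},
      {"id": "male_high_20_north", "sex": "male", "region": "North",
       "age": 20, "rr": 27.19, "ar": 0.85, "expected_pct": 0.15},
      {"id": "male_high_80_midland", "sex": "male", "region": "Midland",
       "age": 80, "rr": 70.31, "ar": 0.85, "expected_pct": 12.19},
      {"id": "male_low_60_midland", "sex": "male", "region": "Midland",
       "age": 60, "rr": 2.59, "ar": 0.85, "expected_pct": 0.30}
    ]
  }
}
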