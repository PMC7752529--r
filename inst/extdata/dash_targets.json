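[
  {
    "nutrient": "total_fat",
    "direction": "max",
    "basis": "percent_of_energy",
    "target": 27,
    "intermediate": 40.5
  },
  {
    "nutrient": "saturated_fat",
    "direction": "max",
    "basis": "percent_of_energy",
    "target": 6,
    "intermediate": 9
  },
  {
    "nutrient": "protein",
    "direction": "min",
    "basis": "percent_of_energy",
    "target": 18,
    "intermediate": 12
  },
  {
    "nutrient": "cholesterol",
    "direction": "max",
    "basis": "per_1000_kcal",
    "target": 71.400000000000006,
    "intermediate": 107.10000000000001
  },
  {
    "nutrient": "fiber",
    "direction": "min",
    "basis": "per_1000_kcal",
    "target": 14.800000000000001,
    "intermediate": 9.8666666666666671
  },
  {
    "nutrient": "magnesium",
    "direction": "min",
    "basis": "per_1000_kcal",
    "target": 238,
    "intermediate": 158.66666666666666
  },
  {
    "nutrient": "calcium",
    "direction": "min",
    "basis": "per_1000_kcal",
    "target": 590,
    "intermediate": 393.33333333333331
  },
  {
    "nutrient": "potassium",
    "direction": "min",
    "basis": "per_1000_kcal",
    "target": 2238,
    "intermediate": 1492
  },
  {
    "nutrient": "sodium",
    "direction": "max",
    "basis": "per_day",
    "target": 2400,
    "intermediate": 3600
  }
]
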