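{
  "response_rate": 0.473,
  "relapse_25wk": 0.13,
  "relapse_per_cycle": 0.065,
  "ae_annual": {
    "fracture": 0.0098,
    "diabetes": 0.0043,
    "cataract": 0.0114,
    "glaucoma": 0.0008,
    "infection": 0.0035
  },
  "utilities_by_age": {
    "age_lo": [35, 45, 55, 65, 75],
    "utility": [0.91, 0.845, 0.795, 0.78, 0.73]
  },
  "ivig_utility_gain": 0.12,
  "fracture": {
    "age_lo": [40, 45, 50, 55, 60, 65, 70],
    "disutility_y1": [0.0833, 0.0971, 0.1047, 0.1068, 0.1094, 0.1113, 0.1212],
    "disutility_post": [0.0293, 0.0324, 0.0349, 0.0371, 0.0391, 0.0412, 0.0425],
    "mortality_y1": [0.0092, 0.0115, 0.0127, 0.0142, 0.0187, 0.026, 0.0541],
    "mortality_post": [0.0001, 0.0001, 0.0001, 0.0002, 0.0003, 0.0006, 0.0018],
    "cost_y1": [3926, 4643, 5041, 5159, 5302, 7901, 10880],
    "cost_post": [63, 68, 73, 78, 83, 87, 744]
  },
  "diabetes": {
    "age_lo": [40, 45, 50, 55, 60, 65, 70],
    "disutility_y1": [0.000179, 0.000173, 0.00016, 7.4e-05, 4e-05, 3e-06, 0.000128],
    "disutility_post": [0.000333, 0.000247, 0.000263, 0.000681, 0.000727, 0.000618, 0.000754],
    "mortality_y1": [0.00039, 0.000715, 0.000875, 0.00116, 0.001525, 0.002025, 0.002645],
    "mortality_post": [0.00032, 0.000285, 0.000685, 0.00032, 0.000755, 0.001035, 0.00085],
    "cost_y1": [12, 13, 16, 21, 24, 25, 27],
    "cost_post": [24, 32, 55, 93, 151, 260, 341]
  },
  "cataract_disutility_wait": 0.38,
  "cataract_disutility_post": 0.1,
  "cataract_wait_days": 109,
  "cataract_cost": 6218,
  "glaucoma_disutility": 0.061,
  "glaucoma_cost": 152,
  "infection_cost": 24334,
  "infection_mortality_lt65": 0.018,
  "infection_mortality_ge65": 0.111,
  "ivig_cost_per_gram": 59.19,
  "nurse_rate_per_hour": 32,
  "nurse_hours_per_administration": 3.5,
  "steroid_cycle_costs": [
    51.19,
    43.57,
    39.87
  ],
  "prednisone_50mg_pill": 0.0913,
  "prednisone_5mg_pill": 0.022,
  "etidronate_kit": 19.99,
  "pharmacy_markup": 0.08,
  "dispensing_fee": 7,
  "life_table": {
    "age": [35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60, 61, 62, 63, 64, 65, 66, 67, 68, 69, 70, 71, 72, 73, 74, 75, 76, 77, 78, 79, 80, 81, 82, 83, 84, 85, 86, 87, 88, 89, 90, 91, 92, 93, 94, 95, 96, 97, 98, 99, 100],
    "annual_death_prob": [0.0008954, 0.0009624, 0.0010358, 0.0011163, 0.0012046, 0.0013013, 0.0014074, 0.0015237, 0.0016511, 0.0017909, 0.001944, 0.0021119, 0.002296, 0.0024977, 0.0027189, 0.0029613, 0.003227, 0.0035182, 0.0038373, 0.0041872, 0.0045705, 0.0049907, 0.0054511, 0.0059557, 0.0065086, 0.0071144, 0.0077782, 0.0085054, 0.0093021, 0.0101749, 0.0111308, 0.0121778, 0.0133245, 0.0145801, 0.0159548, 0.0174599, 0.0191073, 0.0209103, 0.0228833, 0.0250418, 0.0274028, 0.0299847, 0.0328077, 0.0358931, 0.0392647, 0.0429475, 0.0469691, 0.0513587, 0.0561482, 0.0613713, 0.0670646, 0.0732669, 0.0800195, 0.0873662, 0.0953535, 0.1040302, 0.1134474, 0.1236584, 0.1347183, 0.1466836, 0.1596119, 0.1735611, 0.1885885, 0.2047502, 0.2220996, 0.2406862]
  }
}
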