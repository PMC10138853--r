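{
  "_comment": "SYNTHETIC placeholder scoring constants for the three empowerment domains. These are NOT the published SWPER Global principal-component loadings, centering constants or tertile cutpoints; they are plausible stand-ins for testing and examples only. Paste the published constants over these values before any real analysis.",
  "loadings": {
    "attitude_to_violence": {
      "beat_goes_out": 0.45, "beat_neglects_children": 0.44, "beat_argues": 0.46,
      "beat_refuses_sex": 0.42, "beat_burns_food": 0.41,
      "freq_reading": 0.05, "education_years": 0.04, "age_first_cohabitation": 0.02,
      "age_first_birth": 0.02, "age_difference": 0.0, "education_difference": 0.01,
      "decide_healthcare": 0.0, "decide_purchases": 0.0, "decide_visits": 0.0
    },
    "social_independence": {
      "beat_goes_out": 0.02, "beat_neglects_children": 0.02, "beat_argues": 0.02,
      "beat_refuses_sex": 0.02, "beat_burns_food": 0.02,
      "freq_reading": 0.35, "education_years": 0.5, "age_first_cohabitation": 0.3,
      "age_first_birth": 0.3, "age_difference": 0.1, "education_difference": 0.25,
      "decide_healthcare": 0.02, "decide_purchases": 0.02, "decide_visits": 0.02
    },
    "decision_making": {
      "beat_goes_out": 0.01, "beat_neglects_children": 0.01, "beat_argues": 0.01,
      "beat_refuses_sex": 0.01, "beat_burns_food": 0.01,
      "freq_reading": 0.03, "education_years": 0.05, "age_first_cohabitation": 0.02,
      "age_first_birth": 0.02, "age_difference": 0.01, "education_difference": 0.02,
      "decide_healthcare": 0.55, "decide_purchases": 0.5, "decide_visits": 0.52
    }
  },
  "centers": {
    "beat_goes_out": 0.5, "beat_neglects_children": 0.5, "beat_argues": 0.5,
    "beat_refuses_sex": 0.5, "beat_burns_food": 0.5,
    "freq_reading": 0.6, "education_years": 3.5, "age_first_cohabitation": 17.0,
    "age_first_birth": 19.0, "age_difference": -6.0, "education_difference": -1.5,
    "decide_healthcare": 1.0, "decide_purchases": 1.0, "decide_visits": 1.0
  },
  "scales": {
    "beat_goes_out": 0.5, "beat_neglects_children": 0.5, "beat_argues": 0.5,
    "beat_refuses_sex": 0.5, "beat_burns_food": 0.5,
    "freq_reading": 0.75, "education_years": 4.0, "age_first_cohabitation": 4.0,
    "age_first_birth": 4.0, "age_difference": 7.0, "education_difference": 4.0,
    "decide_healthcare": 0.8, "decide_purchases": 0.8, "decide_visits": 0.8
  },
  "cutpoints": {
    "attitude_to_violence": [-0.7, 0.7],
    "social_independence": [-0.6, 0.6],
    "decision_making": [-0.8, 0.8]
  },
  "ranges": {
    "beat_goes_out": [0, 1], "beat_neglects_children": [0, 1], "beat_argues": [0, 1],
    "beat_refuses_sex": [0, 1], "beat_burns_food": [0, 1],
    "freq_reading": [0, 2], "education_years": [0, 25],
    "age_first_cohabitation": [8, 49], "age_first_birth": [8, 49],
    "age_difference": [-40, 40], "education_difference": [-25, 25],
    "decide_healthcare": [0, 2], "decide_purchases": [0, 2], "decide_visits": [0, 2]
  }
}
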