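{
  "n_patients": 4180,
  "profiles": ["A", "B", "C", "D", "E"],
  "profile_mixing": {
    "A": 0.186363636363636,
    "B": 0.179186602870813,
    "C": 0.17200956937799,
    "D": 0.261244019138756,
    "E": 0.201196172248804
  },
  "feature_probs": {
    "male": [0.391, 0.753, 0.955, 0.78, 0.164],
    "custody": [0.09, 0.131, 0.943, 0.097, 0.081],
    "workplace_violence": [0.157, 0.06, 0.006, 0.095, 0.011],
    "intimate_partner_violence": [0.098, 0.012, 0.042, 0.014, 0.806],
    "intrafamily_violence": [0.094, 0.059, 0.047, 0.034, 0.125],
    "police_violence": [0.014, 0.033, 0.789, 0.005, 0],
    "violence_against_police": [0.08, 0.073, 0.006, 0.104, 0],
    "violent_robbery": [0.055, 0.1, 0, 0.03, 0.001],
    "other_violence": [0.42, 0.104, 0.074, 0.689, 0.051],
    "osteoarticular_lesions": [0.099, 0.109, 0.031, 0.12, 0.051],
    "wounds": [0.078, 0.766, 0.702, 0.735, 0.598],
    "bruises_hematomas": [0.149, 0.768, 0.713, 0.772, 0.75],
    "no_somatic_lesion": [0.691, 0.029, 0.071, 0, 0.064],
    "assailant_classmate": [0.024, 0.013, 0, 0.033, 0.004],
    "assailant_coworker": [0.032, 0.016, 0.006, 0.028, 0.005],
    "assailant_partner": [0.108, 0.015, 0.047, 0.016, 0.831],
    "assailant_family": [0.104, 0.055, 0.046, 0.042, 0.118],
    "assailant_unknown": [0.457, 0.619, 0.042, 0.522, 0],
    "assailant_police": [0.014, 0.027, 0.779, 0.001, 0],
    "assailant_neighbor": [0.049, 0.044, 0.019, 0.077, 0.017],
    "assailant_nonspecific": [0.019, 0.008, 0.019, 0.027, 0],
    "assailant_other_known": [0.193, 0.203, 0.042, 0.255, 0.026],
    "loc_shop": [0.023, 0.027, 0.017, 0.046, 0.004],
    "loc_assailant_home": [0.015, 0.013, 0.004, 0.016, 0.019],
    "loc_conjugal_home": [0.041, 0.001, 0.025, 0.003, 0.449],
    "loc_family_home": [0.094, 0.04, 0.042, 0.028, 0.176],
    "loc_own_home": [0.103, 0.055, 0.053, 0.085, 0.153],
    "loc_school": [0.019, 0.008, 0.001, 0.028, 0],
    "loc_detention": [0.006, 0.008, 0.082, 0.011, 0],
    "loc_workplace": [0.161, 0.081, 0.008, 0.106, 0.012],
    "loc_public_building": [0.071, 0.072, 0.083, 0.095, 0.021],
    "loc_residential_common": [0.057, 0.055, 0.053, 0.084, 0.036],
    "loc_public_transport": [0.035, 0.027, 0.017, 0.03, 0.002],
    "loc_private_vehicle": [0.006, 0.001, 0.011, 0.007, 0.008],
    "loc_street": [0.349, 0.602, 0.567, 0.427, 0.093],
    "loc_other": [0.021, 0.009, 0.036, 0.032, 0.026],
    "multiple_assailants": [0.169, 0.781, 0.346, 0.084, 0.023],
    "weapon_threat": [0.049, 0.056, 0.035, 0.045, 0.048],
    "weapon_use": [0.096, 0.212, 0.182, 0.182, 0.127],
    "beating_face": [0.258, 0.665, 0.41, 0.655, 0.665],
    "blows_fall": [0.176, 0.722, 0.328, 0.23, 0.265],
    "knocked_ground": [0.017, 0.18, 0.093, 0.046, 0.065],
    "repeated_assault": [0.185, 0.091, 0.049, 0.084, 0.807],
    "sequestration": [0.003, 0.009, 0, 0.006, 0.005]
  },
  "feature_blocks": {
    "patient": ["male", "custody"],
    "assault_type": ["workplace_violence", "intimate_partner_violence", "intrafamily_violence", "police_violence", "violence_against_police", "violent_robbery", "other_violence"],
    "physical_trauma": ["osteoarticular_lesions", "wounds", "bruises_hematomas", "no_somatic_lesion"],
    "assailants": ["assailant_classmate", "assailant_coworker", "assailant_partner", "assailant_family", "assailant_unknown", "assailant_police", "assailant_neighbor", "assailant_nonspecific", "assailant_other_known"],
    "locations": ["loc_shop", "loc_assailant_home", "loc_conjugal_home", "loc_family_home", "loc_own_home", "loc_school", "loc_detention", "loc_workplace", "loc_public_building", "loc_residential_common", "loc_public_transport", "loc_private_vehicle", "loc_street", "loc_other"],
    "assault_characteristics": ["multiple_assailants", "weapon_threat", "weapon_use", "beating_face", "blows_fall", "knocked_ground", "repeated_assault", "sequestration"]
  },
  "age_params": {
    "A": {
      "median": 32,
      "q1": 23,
      "q3": 41
    },
    "B": {
      "median": 29,
      "q1": 19,
      "q3": 39
    },
    "C": {
      "median": 22,
      "q1": 18,
      "q3": 28
    },
    "D": {
      "median": 33,
      "q1": 25,
      "q3": 43
    },
    "E": {
      "median": 31,
      "q1": 26,
      "q3": 40
    }
  },
  "age_min": 10,
  "delay_params": {
    "A": {
      "median": 48,
      "q1": 24,
      "q3": 81
    },
    "B": {
      "median": 48,
      "q1": 24,
      "q3": 72
    },
    "C": {
      "median": 5,
      "q1": 3,
      "q3": 9
    },
    "D": {
      "median": 48,
      "q1": 24,
      "q3": 72
    },
    "E": {
      "median": 48,
      "q1": 24,
      "q3": 72
    }
  },
  "n_physicians": 10,
  "caseload_weights": [0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1],
  "profile_affinity": null,
  "scale_means": {
    "pain_assault": [4, 4, 3, 4, 4],
    "pain_consult": [2, 3, 3, 3, 3],
    "fear_assault": [5, 5, 3, 5, 6],
    "fear_consult": [3, 3, 0, 3, 5],
    "threat_assault": [0, 3, 0, 0, 4],
    "threat_consult": [0, 0, 0, 0, 2],
    "functional_impairment": [1, 2, 0, 1, 1],
    "interaction_quality": [5, 5, 5, 5, 5],
    "psychosomatic_index": [3, 3, 1, 3, 3]
  },
  "symptom_probs": {
    "sleep_disorder": [0.074, 0.092, 0.007, 0.071, 0.113],
    "loss_of_appetite": [0.045, 0.048, 0.003, 0.031, 0.071],
    "stress_symptoms": [0.098, 0.103, 0.013, 0.085, 0.094],
    "pain_mention": [0.281, 0.375, 0.285, 0.31, 0.331],
    "fear_mention": [0.114, 0.124, 0.014, 0.08, 0.137]
  },
  "rater_bias_sd": 0.3,
  "rater_noise_sd": 1,
  "patient_noise_sd": 3,
  "tiw_coefs": {
    "intercept": -1,
    "sd": 2,
    "coefs": {
      "pain_assault": 0.68,
      "fear_assault": 0.33,
      "threat_assault": 0.33
    }
  },
  "missing_rate": 0,
  "typo_rate": 0.1,
  "unintentional_rate": 0,
  "second_eval_rate": 0
}
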