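{
  "arms": {
    "low_dose": {
      "p_discontinue_ae": 0.023,
      "p_posthoc": 0.405,
      "p_partial": 0.333,
      "daily_dose_mg": 5
    },
    "high_dose": {
      "p_discontinue_ae": 0.156,
      "p_posthoc": 0.571,
      "p_partial": 0.314,
      "daily_dose_mg": 10
    },
    "placebo": {
      "p_discontinue_ae": 0.023,
      "p_posthoc": 0.167,
      "p_partial": 0.548,
      "daily_dose_mg": 0
    }
  },
  "econ": {
    "weekly_direct_medical_cost": 31.5,
    "drug_price_per_5mg": 0.72,
    "horizon_weeks": 52,
    "ae_treatment_weeks": 8,
    "days_per_horizon": 364,
    "discount_rate": 0
  },
  "util": {
    "u_posthoc": 0.934,
    "u_partial": 0.919,
    "u_nonresponse": 0.902,
    "disutility_ae": -0.09,
    "baseline_ygtss_total": 30.37,
    "mapping_intercept": 0.9881,
    "mapping_slope": -0.0035,
    "ae_utility_convention": "baseline_minus_disutility"
  },
  "wtp": 36832.95
}
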