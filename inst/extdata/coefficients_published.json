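{
  "provenance": "Published pooled-trial risk-factor time-path equations, printed 3-decimal precision; dynamic-equation variance components not published (set to 0)",
  "partial": false,
  "dynamic": {
    "hdl": {
      "risk_factor": "hdl",
      "phi0": 0.188, "phi1": 0.238, "phi2": 0.506, "phi3": 0.055,
      "phi4_white": 0.019, "phi4_black": 0.045, "phi4_asian": 0.015,
      "phi5": 0.001, "phi6": -0.001, "resid_sd": 0, "re_sd": 0
    },
    "ldl": {
      "risk_factor": "ldl",
      "phi0": 1.027, "phi1": 0.295, "phi2": 0.383, "phi3": 0.100,
      "phi4_white": -0.001, "phi4_black": 0.032, "phi4_asian": -0.037,
      "phi5": -0.004, "phi6": -0.037, "resid_sd": 0, "re_sd": 0
    },
    "sbp": {
      "risk_factor": "sbp",
      "phi0": 56.461, "phi1": 0.271, "phi2": 0.291, "phi3": 0.356,
      "phi4_white": 0.365, "phi4_black": 0.780, "phi4_asian": -0.416,
      "phi5": 0.027, "phi6": 0.034, "resid_sd": 0, "re_sd": 0
    },
    "hba1c": {
      "risk_factor": "hba1c",
      "phi0": 2.945, "phi1": 0.456, "phi2": 0.243, "phi3": 0.031,
      "phi4_white": -0.082, "phi4_black": 0.065, "phi4_asian": -0.091,
      "phi5": -0.012, "phi6": 0.083, "resid_sd": 0, "re_sd": 0
    },
    "haemoglobin": {
      "risk_factor": "haemoglobin",
      "phi0": 3.698, "phi1": 0.329, "phi2": 0.462, "phi3": -0.177,
      "phi4_white": -0.037, "phi4_black": -0.208, "phi4_asian": -0.081,
      "phi5": -0.010, "phi6": -0.096, "resid_sd": 0, "re_sd": 0
    },
    "heart_rate": {
      "risk_factor": "heart_rate",
      "phi0": 30.755, "phi1": 0.283, "phi2": 0.346, "phi3": 0.560,
      "phi4_white": 0.316, "phi4_black": 0.376, "phi4_asian": 1.389,
      "phi5": -0.059, "phi6": -0.186, "resid_sd": 0, "re_sd": 0
    },
    "bmi": {
      "risk_factor": "bmi",
      "phi0": 1.219, "phi1": 0.684, "phi2": 0.289, "phi3": 0.039,
      "phi4_white": 0.022, "phi4_black": -0.079, "phi4_asian": -0.078,
      "phi5": -0.008, "phi6": 0.000, "resid_sd": 0, "re_sd": 0
    }
  },
  "survival": {
    "AF": {
      "outcome": "AF",
      "distribution": "weibull",
      "ln_gamma": 0.191,
      "betas": {
        "constant": -11.269,
        "age_at_rand": 0.060,
        "female": -0.576,
        "eth_white": 1.073,
        "eth_black": 1.150,
        "lag:bmi": 0.058,
        "lag:hdl": -0.487
      },
      "covariate_spec": ["age_at_rand", "female", "eth_white", "eth_black",
                         "lag:bmi", "lag:hdl"]
    },
    "ALB": {
      "outcome": "ALB",
      "distribution": "weibull",
      "ln_gamma": 0.204,
      "betas": {
        "constant": -8.590,
        "age_at_rand": 0.011,
        "female": -0.298,
        "eth_white": 0.291,
        "lag:bmi": 0.028,
        "lag:sbp": 0.011,
        "lag:hba1c": 0.102
      },
      "covariate_spec": ["age_at_rand", "female", "eth_white", "lag:bmi",
                         "lag:sbp", "lag:hba1c"]
    },
    "PVD": {
      "outcome": "PVD",
      "distribution": "weibull",
      "ln_gamma": 0.443,
      "betas": {
        "constant": -11.596,
        "age_at_rand": 0.030,
        "eth_white": 1.120,
        "smoker_baseline": 0.465,
        "lag:hba1c": 0.151
      },
      "covariate_spec": ["age_at_rand", "eth_white", "smoker_baseline",
                         "lag:hba1c"]
    },
    "EGFR_LT60": {
      "outcome": "EGFR_LT60",
      "distribution": "weibull",
      "ln_gamma": 0.078,
      "betas": {
        "constant": 0.706,
        "first:egfr": -0.037,
        "lag:egfr": -0.032
      },
      "covariate_spec": ["first:egfr", "lag:egfr"]
    }
  },
  "tobit": {
    "below60": {
      "regime": "below60",
      "sigma": 11.888,
      "lower_limit": 0,
      "upper_limit": 60,
      "betas": {
        "constant": 36.058,
        "age_at_rand": -0.100,
        "first:egfr": 0.232,
        "lag:egfr": 0.459,
        "lag:sbp": -0.025,
        "ln_duration": -1.335
      }
    },
    "atabove60": {
      "regime": "atabove60",
      "sigma": 13.839,
      "lower_limit": 60,
      "upper_limit": null,
      "betas": {
        "constant": 36.317,
        "age_at_rand": -0.230,
        "first:egfr": 0.446,
        "lag:egfr": 0.303,
        "lag:sbp": -0.011,
        "ln_duration": -0.753
      }
    }
  }
}
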