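{
  "label": "proestrus",
  "Cm_pF": 17.62,
  "leak": { "g_nS": 0.88, "E_mV": -70.0 },
  "Ihold_pA": 0.0,
  "VT_mV": 26.21,
  "channels": {
    "slow": {
      "gbar_nS": 42.0, "law": "ghk", "E_mV": -92.0, "r": 1,
      "m": { "V50": -3.71, "K": -9.01, "sign": "V_minus_V50",
             "tau": { "form": "double_sigmoid", "A": 1.40, "B": 0.66, "C": 20.02, "D": -0.20, "E": 8.67, "F": -8.10, "G": 10.50 } },
      "inactivation": [
        { "V50": -40.51, "K": 8.41, "sign": "V_minus_V50", "weight": 1.0,
          "tau": { "form": "double_sigmoid", "A": 64.50, "B": 873.09, "C": 46.89, "D": -6.42, "E": 1.34, "F": -8.26, "G": 1.82 } }
      ]
    },
    "fast": {
      "gbar_nS": 45.7, "law": "ghk", "E_mV": -92.0, "r": 1,
      "m": { "V50": -19.22, "K": -7.84, "sign": "V_minus_V50",
             "tau": { "form": "single_sigmoid", "A": 0.47, "B": 0.00, "C": -8.68, "D": 7.88 } },
      "inactivation": [
        { "V50": -57.13, "K": 6.33, "sign": "V_minus_V50", "weight": 0.5,
          "tau": { "form": "constant", "fixed_value": 14.55 } },
        { "V50": -57.13, "K": 6.33, "sign": "V_minus_V50", "weight": 0.5,
          "tau": { "form": "constant", "fixed_value": 113.55 } }
      ]
    },
    "resid": {
      "gbar_nS": 32.9, "law": "ghk", "E_mV": -92.0, "r": 1,
      "m": { "V50": -5.54, "K": -8.85, "sign": "V_minus_V50",
             "tau": { "form": "double_sigmoid", "A": 0.93, "B": 16.39, "C": 44.02, "D": -0.33, "E": 0.13, "F": -6.77, "G": 7.76 } },
      "inactivation": [
        { "V50": -39.16, "K": 11.29, "sign": "V_minus_V50", "weight": 1.0,
          "tau": { "form": "double_sigmoid", "A": 64.50, "B": 1401.65, "C": 59.77, "D": -6.42, "E": 1.34, "F": -8.26, "G": 1.82 } }
      ]
    },
    "nap": {
      "gbar_nS": 0.20, "law": "ohmic", "E_mV": 50.0, "r": 1,
      "m": { "V50": 50.45, "K": -3.72, "sign": "V_plus_V50",
             "tau": { "form": "constant", "fixed_value": 0.40 } },
      "inactivation": [
        { "V50": 31.84, "K": 3.20, "sign": "V_plus_V50", "weight": 1.0,
          "tau": { "form": "bell", "A": 67.30, "B": -27.50, "C": 67.30, "D": 27.50, "E": 3980.90, "F": 62.48 } }
      ]
    },
    "cat": {
      "gbar_nS": 2.0, "law": "ohmic", "E_mV": 155.0, "r": 2,
      "m": { "V50": -54.87, "K": -5.45, "sign": "V_minus_V50",
             "tau": { "form": "single_sigmoid", "A": 1.85, "B": 1.65, "C": -60.60, "D": 5.00 } },
      "inactivation": [
        { "V50": -74.00, "K": 10.90, "sign": "V_minus_V50", "weight": 1.0,
          "tau": { "form": "single_sigmoid", "A": 15.58, "B": 70.15, "C": -57.50, "D": 3.61 } }
      ]
    },
    "hcn": {
      "gbar_nS": 0.64, "law": "ohmic", "E_mV": -19.9, "r": 1,
      "m": { "V50": -97.55, "K": 4.19, "sign": "V_minus_V50",
             "tau": { "form": "single_sigmoid", "A": 201.00, "B": 0.00, "C": -2.20, "D": -5.95 } },
      "inactivation": []
    }
  },
  "nat": {
    "gbar_nS": 68.12, "E_mV": 50.0, "open_exponent": 3,
    "alpha": { "s": 65.24, "k": -6.05, "r": 38.40 },
    "beta":  { "s": 48.59, "k": 5.09,  "r": 391.84 },
    "r1":    { "s": 9.52,  "k": -4.66, "r": 1.36 },
    "r3":    { "s": 12.68, "k": 3.08,  "r": 0.014 }
  }
}
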