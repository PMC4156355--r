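{
  "comment": "Heart-failure ionic remodeling factors, expressed as scale factors relative to the normal model (1.0 = unchanged). 'homogeneous' applies to every cell class; 'heterogeneous' overrides I_NCX and/or J_SERCA with class-specific values.",
  "GPB": {
    "homogeneous": {
      "I_NaL": 2.00,
      "tau_hL": 2.00,
      "I_to": 0.40,
      "I_K1": 0.68,
      "I_NaK": 0.90,
      "I_Nab": 0.00,
      "I_Cab": 1.53,
      "I_NCX": 1.75,
      "J_SERCA": 0.50,
      "I_leak": 3.00,
      "EC_50SR": 0.89
    },
    "heterogeneous": {
      "I_NCX": { "EPI": 2.00, "MID": 1.60, "ENDO": 1.60 },
      "J_SERCA": { "EPI": 0.75, "MID": 0.60, "ENDO": 0.45 }
    }
  },
  "ORd": {
    "homogeneous": {
      "I_NaL": 1.80,
      "tau_hL": 1.80,
      "I_to": 0.40,
      "I_K1": 0.68,
      "I_NaK": 0.70,
      "I_Nab": 1.00,
      "I_NCX": 1.75,
      "J_SERCA": 0.50,
      "I_leak": 1.30,
      "CaMKa": 1.50,
      "Jrel_NP_Ca_sens": 0.80
    },
    "heterogeneous": {
      "I_NCX": { "EPI": 2.00, "MID": 1.60, "ENDO": 1.60 },
      "J_SERCA": { "EPI": 0.75, "MID": 0.60, "ENDO": 0.45 }
    }
  }
}
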