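{
  "units": {
    "k_tilde": "1/min", "gamma": "1/min", "k_DT": "1/min", "psi": "1/min",
    "sigma": "dimensionless", "l_max": "um"
  },
  "note": "Condition presets for the microwell turnover model. The 'fitted' family carries the rates from the numerical fit including aging; the '_deduced' family carries the rounded rates read off the steady-state ratio arithmetic (no aging). Each preset records the l_max its source calculation used; the three l_max scales (120 for assembly saturation at 60 um, 60 for steady-state ratios, 110 for the experimental pool) are deliberately not reconciled.",
  "presets": {
    "assembly":            {"k_tilde": 0.01, "gamma": 0,     "k_DT": 0,    "psi": 0,     "sigma": 1, "l_max": 120},
    "disassembly":         {"k_tilde": 0.01, "gamma": 0.02,  "k_DT": 0.02, "psi": 0.002, "sigma": 0, "l_max": 60},
    "recycling":           {"k_tilde": 0.01, "gamma": 0.12,  "k_DT": 0.2,  "psi": 0.001, "sigma": 0, "l_max": 60},
    "disassembly_deduced": {"k_tilde": 0.01, "gamma": 0.015, "k_DT": 0.03, "psi": 0,     "sigma": 0, "l_max": 60},
    "recycling_deduced":   {"k_tilde": 0.01, "gamma": 0.06,  "k_DT": 0.2,  "psi": 0,     "sigma": 0, "l_max": 60}
  }
}
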