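{
  "version": "1.0",
  "description": "Stage- and species-specific physiological constants for the renal-failure extrapolation pipeline. RBF in mL/min/kg, fu dimensionless, reference body weights in kg, eGFR windows in mL/min/1.73m2, demographic ranges as [min, max].",
  "species": {
    "human": {
      "fu": 0.61,
      "reference_bw": 76,
      "rbf": { "normal": 18.0, "moderate": 5.24, "severe": 3.83 }
    },
    "rat": {
      "fu": 0.793,
      "reference_bw": 0.28,
      "rbf": { "normal": 33.3, "moderate": 28.0, "severe": 18.0 }
    }
  },
  "egfr_windows": {
    "normal": { "min": 90.0, "max": 120.0, "closed": true },
    "moderate": { "min": 27.13, "max": 54.25, "closed": false },
    "severe": { "min": 12.97, "max": 25.94, "closed": true }
  },
  "demographics": {
    "normal": {
      "age_years": [37, 65],
      "height_cm": [165, 193],
      "weight_kg": [65, 87],
      "bmi_kg_m2": [21, 29]
    },
    "moderate": {
      "age_years": [37, 63],
      "height_cm": [160, 175],
      "weight_kg": [65, 116],
      "bmi_kg_m2": [23, 41]
    },
    "severe": {
      "age_years": [31, 72],
      "height_cm": [155, 175],
      "weight_kg": [74, 109],
      "bmi_kg_m2": [27, 40]
    }
  }
}
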