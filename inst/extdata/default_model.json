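{
  "products": [
    {
      "name": "Polycose",
      "kind": "carbohydrate",
      "form": "powder",
      "potency": 0.94,
      "water_per_unit": 0,
      "linear_coeff": 20
    },
    {
      "name": "Protein1",
      "kind": "protein",
      "form": "powder",
      "potency": 0.857,
      "water_per_unit": 0,
      "linear_coeff": 4
    },
    {
      "name": "Protein2",
      "kind": "protein",
      "form": "powder",
      "potency": 0.8,
      "water_per_unit": 0,
      "linear_coeff": 38
    },
    {
      "name": "Microlipid",
      "kind": "fat",
      "form": "emulsion",
      "potency": 0.5,
      "water_per_unit": 0.5,
      "linear_coeff": -1.7
    },
    {
      "name": "HMF1",
      "kind": "hmf",
      "form": "sachet",
      "potency": 0,
      "dose_offset": 106,
      "sachets_per_dose": 4
    },
    {
      "name": "HMF2",
      "kind": "hmf",
      "form": "sachet",
      "potency": 0,
      "dose_offset": 56,
      "sachets_per_dose": 4
    }
  ],
  "storage_factor": 1.04,
  "storage_mode": "flat",
  "storage_slope": 9,
  "safety_limit": 450,
  "qc_threshold": 22,
  "water_mass": 87.5,
  "hmf_composition": {
    "HMF1": {"fat": 0.36, "protein": 1.0, "carbohydrate": 1.8},
    "HMF2": {"fat": 1.04, "protein": 1.1, "carbohydrate": 1.2}
  },
  "target_profile": {"fat": 4.4, "protein": 3.0, "carbohydrate": 8.8}
}
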