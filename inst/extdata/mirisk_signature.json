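{
  "features": [
    {"mirna": "miR-2115-3p", "weight": 1.870},
    {"mirna": "miR-218-5p", "weight": 0.907},
    {"mirna": "miR-224-5p", "weight": 0.495},
    {"mirna": "miR-4676-3p", "weight": 1.309},
    {"mirna": "miR-6503-5p", "weight": 1.159}
  ],
  "cutpoint": 5.61,
  "transform": "ln1p",
  "provenance": "published miRisk score (frozen coefficients and median cutpoint)"
}
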