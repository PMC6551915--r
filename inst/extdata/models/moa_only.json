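{
  "name": "MOA_ONLY",
  "intercept": 0.042,
  "coefficients": {
    "MCF7_ENSG00000185950": 3.84,
    "MCF7_ENSG00000112115": -11.163,
    "MCF7_ENSG00000135100": -0.758,
    "PC3_ENSG00000128228": 0.193,
    "PC3_ENSG00000168209": 0.0007,
    "PC3_ENSG00000110619": 0.04,
    "PC3_ENSG00000064687": -0.755,
    "PC3_ENSG00000168875": -1.31,
    "PC3_ENSG00000276644": -9.301
  },
  "alpha": 0.16,
  "gamma": 0.16,
  "feature_kinds": {
    "MCF7_ENSG00000185950": "GENE",
    "MCF7_ENSG00000112115": "GENE",
    "MCF7_ENSG00000135100": "GENE",
    "PC3_ENSG00000128228": "GENE",
    "PC3_ENSG00000168209": "GENE",
    "PC3_ENSG00000110619": "GENE",
    "PC3_ENSG00000064687": "GENE",
    "PC3_ENSG00000168875": "GENE",
    "PC3_ENSG00000276644": "GENE"
  },
  "lambda": null,
  "training_ids": [],
  "package_version": "0.1.0"
}
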