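{
  "name": "QSMART_FINAL",
  "intercept": -0.372,
  "coefficients": {
    "Mor23i": 0.012,
    "N-072": -0.042,
    "ALOGP": 0.139,
    "MCF7_ENSG00000112115": -2.98,
    "PC3_ENSG00000197646": -0.075,
    "PC3_ENSG00000276644": -0.216
  },
  "alpha": 1.25,
  "gamma": 1.75,
  "feature_kinds": {
    "Mor23i": "MD",
    "N-072": "MD",
    "ALOGP": "MD",
    "MCF7_ENSG00000112115": "GENE",
    "PC3_ENSG00000197646": "GENE",
    "PC3_ENSG00000276644": "GENE"
  },
  "lambda": null,
  "training_ids": [],
  "package_version": "0.1.0"
}
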