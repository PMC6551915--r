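{
  "name": "MD_ONLY",
  "intercept": -0.335,
  "coefficients": {
    "Mor23i": 0.077,
    "R8s+": -0.012,
    "C-040": 0.007,
    "N-072": -0.061,
    "ALOGP": 0.062,
    "CATS3D_06_AP": -0.003,
    "piPC08": 0.0006,
    "GATS2i": -0.01,
    "SpMax1_Bh(v)": 0.001
  },
  "alpha": 0.11,
  "gamma": 0.11,
  "feature_kinds": {
    "Mor23i": "MD",
    "R8s+": "MD",
    "C-040": "MD",
    "N-072": "MD",
    "ALOGP": "MD",
    "CATS3D_06_AP": "MD",
    "piPC08": "MD",
    "GATS2i": "MD",
    "SpMax1_Bh(v)": "MD"
  },
  "lambda": null,
  "training_ids": [],
  "package_version": "0.1.0"
}
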