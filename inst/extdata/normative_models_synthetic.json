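{
  "comment": "SYNTHETIC illustration models for diameter Z-scores: linear normative mean and constant SD in the BSA predictor. These are NOT published regressions; supply your own normative_model() for clinical use.",
  "models": [
    {
      "site": "sinus",
      "predictor": "BSA",
      "mean_coef": [13.5, 9.0],
      "sd_coef": [2.0],
      "range": [0.3, 2.6],
      "source": "synthetic_example"
    },
    {
      "site": "proximal_DAo",
      "predictor": "BSA",
      "mean_coef": [8.0, 6.0],
      "sd_coef": [1.6],
      "range": [0.3, 2.6],
      "source": "synthetic_example"
    }
  ]
}
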