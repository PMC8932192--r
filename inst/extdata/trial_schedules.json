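{
  "provenance": "External trial constants: dose schedules of three randomised trials comparing moderately hypofractionated with conventionally fractionated prostate radiotherapy. These values are protocol constants of the named trials, packaged here as an editable configuration; they are inputs of the BED re-analysis, not outputs of any fit.",
  "trials": [
    {
      "trial": "RTOG 0415",
      "hypofractionated": { "total_dose": 70, "n_fractions": 28 },
      "conventional": { "total_dose": 73.8, "n_fractions": 41 }
    },
    {
      "trial": "HYPRO",
      "hypofractionated": { "total_dose": 64.6, "n_fractions": 19 },
      "conventional": { "total_dose": 78, "n_fractions": 39 }
    },
    {
      "trial": "Fox Chase",
      "hypofractionated": { "total_dose": 70.2, "n_fractions": 26 },
      "conventional": { "total_dose": 76, "n_fractions": 38 }
    }
  ]
}
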