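{
  "provenance": "Transcribed from the published source's per-regimen outcome tables (conventional, moderately hypofractionated and SBRT groups). Each row is one published treatment arm; the quadratic dose column c equals D^2/N (or D*d where only the dose per fraction is reported).",
  "groups": [
    {
      "name": "conventional",
      "file": "conventional.csv",
      "regimen": "conventional",
      "n_arms": 22,
      "n_patients": 7793,
      "note": "1.8-2.1 Gy per fraction; Eade arms carry dose per fraction (2.1 Gy) with no integer fraction number."
    },
    {
      "name": "moderate_hypo",
      "file": "moderate_hypo.csv",
      "regimen": "moderate_hypo",
      "n_arms": 31,
      "n_patients": 6822,
      "note": "2.19-3.5 Gy per fraction."
    },
    {
      "name": "sbrt",
      "file": "sbrt.csv",
      "regimen": "sbrt",
      "n_arms": 11,
      "n_patients_pooled_once": 1827,
      "note": ">= 6.5 Gy per fraction. The 385/589/126-patient King rows are risk subsets of the 1100-patient pooled row and are flagged subset_of_pooled; the patient total counts the pooled row once."
    }
  ]
}
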