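{
  "out_dir": "wastingshocks_output",
  "seed": 1,
  "children_csv": null,
  "macro_csv": null,
  "countries_csv": null,
  "projection_csv": null,
  "outcomes": ["wasting_any", "wasting_mod_sev", "wasting_severe"],
  "measures": ["gni", "gdp"],
  "lag": 1,
  "mechanisms": false,
  "elasticity": -0.178,
  "elasticity_ci": null,
  "sim": {
    "n_countries": 40,
    "children_per_round": 2000,
    "beta_true": -0.15,
    "seed": 1
  },
  "verbose": true
}
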