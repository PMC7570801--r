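[
  {
    "name": "carrot",
    "aspect_ratio": 0.9531,
    "density_g_per_ml": 1.0987,
    "n_slices": 8,
    "classes": [
      {"label": "S", "low": 80, "high": 125},
      {"label": "M", "low": 125, "high": 200},
      {"label": "L", "low": 200, "high": 250},
      {"label": "2L", "low": 250, "high": 320}
    ]
  },
  {
    "name": "cucumber",
    "aspect_ratio": 0.9677,
    "density_g_per_ml": 1.019,
    "n_slices": 8,
    "classes": [
      {"label": "S", "low": null, "high": 100},
      {"label": "M", "low": 100, "high": 150},
      {"label": "L", "low": 150, "high": 200, "incl_high": true},
      {"label": "XL", "low": 200, "high": null}
    ]
  }
]
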