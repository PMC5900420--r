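{
  "mode": "regression",
  "n_lv": 9,
  "feature_names": ["704", "534", "673", "568", "505", "734", "524", "949", "446", "594", "452"],
  "coefficients": [484.65, -1018.89, -887.77, 304.06, 1645.31, 354.86, 1092.13, 449.62, -1997.31, -589.93, 1283.3],
  "intercept": -1126.19,
  "x_mean": null,
  "y_mean": null,
  "x_scale": null,
  "metadata": {
    "description": "Published 11-wavelength PLSR calibration equation predicting shikimic acid concentration (fresh-weight units) from maize canopy reflectance; coefficients transcribed from the reported equation.",
    "note": "The 534 nm band was printed as 'X5343 nm' in the source; it is recorded here as 534 nm, matching the reported sensitive-wavelength list (446, 452, 473, 505, 524, 534, 568, 594, 673, 704, 715, 734, 949 nm).",
    "wavelength_units": "nm",
    "response": "shikimic acid concentration, fresh-weight basis"
  }
}
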