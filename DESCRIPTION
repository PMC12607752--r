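Package: hsijam
Title: Hyperspectral Prediction of Sugar Content in Processed Apple Jam
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end visible/near-infrared (VNIR) hyperspectral imaging
    pipeline for estimating sugar concentration (% w/w) in processed apple jam.
    Covers synthetic scene generation with ENVI header/data I/O, white/dark
    reference reflectance calibration, spectral angle mapper (SAM) segmentation,
    region-of-interest grid subdivision into unit-norm mean-spectrum features,
    leakage-aware cultivar- and concentration-based data splits, and three
    regression models: a one-dimensional residual network trained with Adam on
    mean absolute error, a radial-basis-function support vector regressor, and
    gradient-boosted trees with early stopping. Evaluation utilities compute
    R-squared, RMSE, MAE, per-sugar-level error profiles, multi-run sweeps and
    RGB-versus-hyperspectral comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
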