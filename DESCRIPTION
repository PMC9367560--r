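Package: ViSTA
Title: Temporal-Attention Prediction of Lung Adenocarcinoma Invasiveness
    from Irregular Follow-Up CT Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the invasive-adenocarcinoma status of a pulmonary
    nodule from an irregularly sampled series of follow-up CT scans.
    Implements the ViSTA network: a compact 3D convolutional encoder per
    time point followed by SimTA layers, a causal temporal attention
    mechanism whose weights decay exponentially with the elapsed time
    between examinations, so that series with arbitrary scan intervals can
    be classified without resampling to a regular grid. Ships the full
    surrounding pipeline: a synthetic nodule-growth simulator with
    ground-truth invasiveness labels, CT preprocessing (isotropic
    resampling, HU clipping and normalization, patch extraction),
    volume-doubling-time and static/recurrent CNN baselines, a training
    and evaluation harness (AdamW, cosine schedule, ROC/AUC, Youden
    cutoff selection) and gradient saliency visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    RNifti,
    jsonlite,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
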