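Package: sbpmi
Title: Gut Microbiota Dysbiosis Indices and Risk Prediction for
    Spontaneous Bacterial Peritonitis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes gut microbiota-derived dysbiosis indices for
    HBV-related cirrhosis, including the spontaneous bacterial
    peritonitis microbiota-derived index (SBP-MI, a log10 ratio of
    pathobiont to short-chain-fatty-acid-producer genus abundances with
    per-genus pseudocounts) and the hepatitis B cirrhosis dysbiosis
    indicator (HBCDI), together with paired baseline/follow-up delta
    indices.  Provides a from-scratch Firth penalized logistic
    regression engine (Jeffreys-prior penalty, profile-likelihood
    intervals, penalized likelihood-ratio tests), univariable
    P-value screening, ROC analysis with DeLong intervals and Youden
    cutoffs, calibration diagnostics (slope, Brier score,
    Hosmer-Lemeshow), Harrell bootstrap optimism correction, the frozen
    published SBP risk-prediction equation with nomogram points tables,
    and a Dirichlet-based synthetic cohort generator for staged and
    longitudinal microbiome studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    biomformat
Config/testthat/edition: 3
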