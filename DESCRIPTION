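Package: aisleep
Title: Unsupervised Sleep Staging from Single-Channel EEG
Version: 0.1.0
Authors@R:
    person("AISleep", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Automated, interpretable and fully unsupervised sleep staging
    from a single EEG channel. Per-epoch Welch power spectra are embedded
    into two dimensions, and the five AASM stages (Wake, N1, N2, N3, REM)
    are carved out sequentially by competing feature-weighted Gaussian
    kernel density estimates. Features include gamma band power, a
    personalized fast-spindle band derived from the IRASA oscillatory
    residual, slow-oscillation coverage, and oscillatory strength. Includes
    EDF input/output, a seedable generator of ground-truthed synthetic
    overnight recordings, hypnogram evaluation metrics (accuracy, macro F1,
    Cohen's kappa, optimal cluster-label alignment), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    uwot,
    clue,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    cluster
Config/testthat/edition: 3
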