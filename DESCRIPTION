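Package: psmrescore
Title: Cross-Validated Semi-Supervised Rescoring of Peptide-Spectrum Matches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Target-decoy rescoring of shotgun-proteomics peptide-spectrum
    matches (PSMs). Implements false discovery rate and q-value estimation
    from separate target and decoy database searches (including pi0, the
    fraction of incorrect matches among targets), a self-training linear
    support vector machine that combines multiple PSM features into a
    discriminant score, a three-fold cross-validation protocol with nested
    hyperparameter grid search so that every PSM is scored by a model never
    trained on it, per-fold affine score normalization that lets the folds
    be merged into a single calibrated result list, and a simulation
    framework demonstrating that the cross-validation protocol keeps the
    estimated error rates honest while disabling it inflates them.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils, withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), e1071, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
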