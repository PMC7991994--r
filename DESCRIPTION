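Package: phonatory
Title: Phonatory Voice Biomarkers for Detecting Bulbar Involvement in ALS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening bulbar involvement in amyotrophic lateral
    sclerosis (ALS) from sustained-vowel recordings. Implements extraction of
    fifteen phonatory features (the jitter and shimmer perturbation families,
    harmonics-to-noise ratio, and pitch statistics) from mono WAV audio via
    autocorrelation pitch tracking and glottal-cycle analysis; age correction,
    standardization and principal component analysis of the feature table; and
    a six-model supervised classifier suite (support vector machine, neural
    network, linear discriminant analysis, logistic regression, naive Bayes,
    random forest) evaluated by repeated 10-fold cross-validation with
    training-fold upsampling at 50% and 95% decision thresholds. A synthetic
    sustained-vowel generator with controllable jitter, shimmer, noise level
    and cohort structure provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    grid,
    jsonlite,
    MASS,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
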