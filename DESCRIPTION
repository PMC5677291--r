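Package: stresskelm
Title: Stress-Level Classification from Wearable Biosignals with a Kernel
    Extreme Learning Machine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for five-level mental-stress classification from
    photoplethysmogram (PPG), electrodermal activity (EDA) and skin
    temperature (SKT) recordings. Implements the full pipeline: band-pass
    filtering and pulse-peak detection, epoching, a 24-feature panel (15
    heart-rate-variability features across time, frequency and nonlinear
    domains; 6 skin-conductance features from a tonic/phasic deconvolution;
    3 skin-temperature features), extreme learning machine (ELM) and kernel
    ELM (K-ELM) classifiers with ridge-regularized closed-form solutions,
    within-subject leave-one-out cross-validation with (C, gamma) grid
    search, self-organizing map cluster analysis, one-way ANOVA with Tukey
    HSD feature statistics, and a seeded synthetic biosignal generator for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
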