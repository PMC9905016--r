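Package: soundmotion
Title: Behavioral Decomposition of Sound-Evoked Activity in Sensory Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether sound-evoked activity in a visual
    cortical population is explained by the body movements that sounds elicit.
    Provides a ground-truth synthetic session generator (factorial audiovisual
    design, low-rank sound-evoked latent driving both facial motion and Poisson
    spiking at a short lead time), peri-stimulus trial-tensor assembly with
    causal half-Gaussian smoothing and z-scoring, ANOVA-style factorial
    marginalization, cross-validated PCA with a label-shuffling dimensionality
    test, template-matching stimulus decoding, ridge encoding models with
    lagged behavioral predictors, and reduced-rank-regression estimates of the
    movement-related neural subspace, its overlap with the sound-related
    subspace, and movement-to-neural timing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
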