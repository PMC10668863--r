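Package: avistim
Title: Receptor-Noise-Limited Light Stimulus Design and Choice-Test
    Analysis for Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing light stimuli of high chromatic contrast
    to an avian visual system and for analysing repeated-measures
    single-choice behavioural experiments. Implements a spectral data
    model with radiometric and photometric conversions, visual-pigment
    nomogram templates with oil-droplet and ocular-media filtering, the
    receptor-noise-limited model of chromatic discrimination for an
    arbitrary number of cone classes, a peak-shifted LED contrast scan
    with candidate-peak selection and radiometric matching, and a
    mixed-model analysis pipeline for choice trials (ambient-light
    principal components, side-bias diagnostics, a four-step stepwise
    interaction ladder, estimated marginal means, marginal and
    conditional R-squared, and repeatability with parametric bootstrap
    intervals). A synthetic-data module generates spectra and choice
    datasets with the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
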