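Package: sgnc
Title: Stochastic Generative Network Complex for Multi-Target Lead Generation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Latent-space molecular lead generation for multi-target drug
    discovery. Implements a multi-reference Langevin (Ornstein-Uhlenbeck)
    sampler over a molecular latent space, a pluggable encoder/decoder
    contract with a built-in codebook codec and reconstruction-rate
    validation, feed-forward binding-affinity regressors with 10-fold
    cross-validated Pearson R and RMSE reporting, cosine-similarity
    reference selection, and a multi-criteria drug-likeness screening
    cascade (binding-affinity thresholds, Lipinski's rule of five, ADMET
    property-range classification, novelty filtering and percent-excellent
    ranking), together with a synthetic-data module and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
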