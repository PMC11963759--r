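Package: junctionMH
Title: Microhomology-Aware Modeling of Trimming and Ligation in V(D)J
    Recombination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how germline-encoded microhomology biases nucleotide
    trimming and ligation during V(D)J recombination. Enumerates every
    trimming/ligation annotation consistent with an observed junction
    sequence, fits a two-step conditional logit model over latent
    annotations by expectation-maximization, tests microhomology effects
    with bootstrap Wald tests and likelihood-ratio tests, and measures how
    microhomology parameterization changes annotation probabilities and
    rankings. Includes a synthetic-repertoire generator with known
    ground-truth coefficients so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'config.R'
    'germline.R'
    'scenario.R'
    'features.R'
    'model.R'
    'repertoire-data.R'
    'em.R'
    'inference.R'
    'annotation.R'
    'synthetic.R'
    'show-methods.R'
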