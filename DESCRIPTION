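Package: tempreg
Title: Temporal Regularity Perception: Simulated Experiments and Psychophysical Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how the temporal regularity of the environment
    shapes perceived stimulus timing. Generates the factorial trial designs of
    two auditory-sequence psychophysics experiments (regularity judgments of
    five-tone sequences; audiovisual temporal-order judgments of a deviant
    final tone), simulates cohorts of Bayesian observers that recursively
    update a predicted-onset prior and fuse it with noisy sensory evidence,
    estimates the point of subjective simultaneity and just noticeable
    difference with the non-parametric Spearman-Karber method, and fits the
    two-noisy-criteria regularity-judgment model (difference of two cumulative
    Gaussians) by maximum likelihood. Includes an end-to-end replication
    driver with JND-based exclusion and the temporal regularisation index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
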