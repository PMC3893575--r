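Package: vocadev
Title: Intrinsically Motivated Vocal Development Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates early vocal development as curiosity-driven goal
    babbling. A learning agent drives a surrogate articulatory synthesizer
    (area-function vocal tract with lossless-tube formant computation)
    through an overdamped spring-mass motor system, perceives intensity and
    formant averages in two time windows, and learns a joint Gaussian-mixture
    sensorimotor model by incremental expectation-maximization. Goals (and,
    optionally, the choice between self-exploration and emulation of ambient
    sounds) are sampled from a competence-progress interest model, so that a
    developmental sequence of vocalization classes (no phonation,
    unarticulated, articulated) and a late shift toward imitation
    self-organize rather than being preprogrammed. Includes analysis tools
    for windowed class proportions, automatic developmental-stage
    segmentation, per-stage vocalization-type tables, strategy-usage curves
    and outcome-cloud comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    deSolve,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
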