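Package: chronodecomp
Title: Single-Trial Decomposition of Decision EEG into Sequential Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes epoched multichannel EEG recorded between stimulus
    and response into an ordered sequence of short trial-recurrent
    multivariate events (half-sine topographic patterns with
    gamma-distributed inter-event times), estimated by expectation
    maximization with an exact forward-backward pass. Inter-event
    durations are related to stimulus intensity through Pieron's and
    Fechner's psychophysical laws, the latter embedded in a
    proportional-rate diffusion model that jointly predicts mean
    response time and accuracy. Includes a synthetic-data generator
    with known ground truth, event-level statistics (topography
    asymmetry tests, cluster-level permutation tests, single-trial
    build-up regressions), and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
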