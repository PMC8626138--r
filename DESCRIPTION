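Package: seiztrack
Title: Real-Time Seizure State Tracking from Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tracks a continuous latent seizure state from multichannel
    scalp EEG in a causal, real-time-applicable way. Sliding-window FFT
    band powers feed parallel mixed filters, each combining one Gaussian
    continuous feature and one Bernoulli binary feature of a shared AR(1)
    latent state with parameters learned by expectation maximization. The
    parallel state trajectories are fused by a square-root Kalman filter
    whose parameters are learned by a second, linear-Gaussian EM, and the
    fused state is binarized by a cost-weighted linear discriminant.
    Includes EDF reading/writing with seizure-interval annotations, a
    greedy wrapper feature selector scored by validation F1, and synthetic
    EEG/subject generators so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
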