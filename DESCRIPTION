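Package: refractiv
Title: Causal Effective Connectivity from Optogenetic Stimulation via
    Refractoriness-Based Instrumental Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of spiking neurons with a discrete-time
    binomial generalized linear model and estimates causal (effective)
    connectivity between neuron pairs under widefield optogenetic
    stimulation.  The absolute refractory period of the presynaptic
    neuron is used as an instrumental variable, optionally combined with
    a difference-in-differences correction, and compared against
    ordinary least squares and cross-correlogram spike transmission
    baselines.  Includes a one-photon light-transport and opsin
    photocurrent model for distance-dependent stimulation strengths,
    ground-truth calibration, error metrics, condition numbers, and
    AUROC-based classification scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
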