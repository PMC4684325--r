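Package: strfkit
Title: Modular Spectro-Temporal Receptive Field Estimation for Auditory Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Composable encoding-model chains for auditory neurons: a second-order
    gammatone cochlear filterbank with logarithmic compression, linear
    spectro-temporal filters (full FIR, low-rank factorized, and parameterized
    Gaussian/Morlet spectral and difference-of-exponentials/pole-zero temporal
    kernels), optional short-term synaptic plasticity and double-exponential
    output nonlinearities. Models are fitted by nested coordinate descent
    ("boosting") against a jackknife-shrunken normalized mean squared error,
    and evaluated with trial-to-trial noise-corrected prediction correlation,
    response signal-to-noise ratio, infinite-data extrapolation of prediction
    accuracy, and Pareto complexity-versus-performance comparison. Includes a
    seeded synthetic-data module that simulates ground-truth neurons so that
    estimation and evaluation are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
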