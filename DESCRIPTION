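Package: hlnd
Title: Hierarchical Linear-Nonlinear Models of Dendritic Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the input-output transformation of single
    neurons with hierarchical linear-nonlinear (hLN) cascades. Presynaptic
    spike trains are filtered by alpha-function synaptic kernels, summed
    within dendritic subunits, passed through sigmoidal nonlinearities and
    combined along a subunit tree to predict the somatic subthreshold
    membrane potential. Includes staged least-squares fitting with
    near-linear initialisation of the subunit nonlinearities, a multiplexed
    two-channel subunit variant, a Poisson spiking extension with
    raised-cosine adaptation kernels, a generator of in-vivo-like synaptic
    input (orientation-tuned ensemble switching, Ornstein-Uhlenbeck rate
    fluctuations, rate-tracking inhibition), and summary statistics for
    comparing model output with dendritic recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
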