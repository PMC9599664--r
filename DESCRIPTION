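Package: sparsetrack
Title: Sparse Microbial Source Tracking with Unknown-Source Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the mixing proportions of a sink microbiome sample as a
    sparse convex combination of many candidate source samples plus an unknown
    source. Candidate sources are screened with an L1-regularized,
    simplex-constrained least-squares problem; mixing proportions and latent
    taxon profiles are then refined by an expectation-maximization algorithm
    with an exponential sparsity prior on the known-source proportions, and the
    sparsity hyperparameter is chosen by grid search on the model likelihood.
    Includes a multinomial community simulator (Pareto-distributed sparse
    mixtures, fixed-depth subsampling, shuffled-abundance nuisance sources) and
    the evaluation metrics used to benchmark source-tracking accuracy, so the
    whole method can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
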