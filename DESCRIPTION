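Package: alpipe
Title: Active Learning of Measurement Times for Practical Identifiability
    of Dynamic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Sequential optimal experimental design for ordinary
    differential equation models, targeted at establishing practical
    identifiability of the model parameters via profile likelihood.
    Implements the E-ALPIPE acquisition criterion (likelihood-weighted
    disagreement between the maximum-likelihood model and the boundary
    models of a simplified profile-likelihood analysis, scaled by the
    predicted observation-noise variance), the profile-ensemble
    generalized-variance and relative-variance benchmark criteria, and
    random sampling. Provides multi-start box-constrained maximum
    likelihood estimation under a lower-truncated normal noise model,
    bisection search for profile-likelihood confidence intervals, a
    replicated simulation harness with three built-in case studies
    (a sum of two exponential decays and single- and two-output Monod
    microbial growth bioreactor models), and evaluation utilities
    (identifiability probability curves, iterations-to-identifiability,
    confidence-interval widths and trajectory-error summaries with
    Wilcoxon signed-rank comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
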