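Package: ratchetwalk
Title: Random-Walk Approximation of the Flashing Brownian Ratchet and
    Generalized Parrondo Games
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact numerical study of the Brownian ratchet and the flashing
    Brownian ratchet via a lattice random-walk approximation. Provides the
    sawtooth-potential diffusion model, the generalized capital-dependent
    Parrondo games that motivate the approximation, exact probability mass
    function propagation of the approximating walks, peak-area and
    mean-displacement statistics of the resulting densities, the wrapped
    one-flash-period Markov chain with its stationary law and stationary
    mean displacement, and an Euler-Maruyama Monte-Carlo oracle for
    stochastic cross-validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
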