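Package: eradmix
Title: Multinomial-Mixture Modelling of Chemical Eradication Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removal-protocol multinomial-mixture modelling for invasive-ant
    eradication programs that combine monthly trap captures with pesticide
    applications. Provides the joint per-survey probabilities of death by
    pesticide and first capture in a trap, a marginalized multinomial -
    negative-binomial likelihood, Bayesian estimation of latent initial
    abundance and detection/death probabilities by Metropolis-within-Gibbs
    MCMC, posterior survivor trajectories with 95%/99% eradication
    declaration times, a minimum-net-expected-cost optimal stopping rule
    with cost-ratio sensitivity analysis, and an individual-based survey
    simulator emulating the monitoring program.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
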