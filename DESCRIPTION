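Package: sepsisCDSS
Title: Data-Driven POMDP Clinical Decision Support for Sepsis Antibiotic Policies
Version: 0.1.0
Authors@R: person("sepsisCDSS", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Labels sepsis-related patient states from vital signs and blood
    cultures using SIRS-based rules, estimates transition and observation models
    of a partially observable Markov decision process (POMDP) from timestamped
    electronic-health-record trajectories, solves for an optimal antibiotic
    administration policy with a Perseus-style randomized point-based value
    iteration algorithm, and evaluates policy-followed versus not-followed
    outcomes retrospectively with hypergeometric enrichment tests. Includes a
    synthetic EHR cohort generator with known ground truth for end-to-end
    validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    jsonlite,
    MASS,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
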