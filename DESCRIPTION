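Package: admixfit
Title: F-Statistics, qpAdm-Style Admixture Modeling and Admixture-Graph
    Simulation for Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for allele-frequency-based population
    genetic inference from low-coverage ancient DNA. Implements Patterson's
    D and f2/f3/f4 statistics with weighted block-jackknife standard
    errors, individual-label permutation nulls with empirical P-values,
    qpWave-style rank tests and qpAdm-style admixture-proportion
    estimation with model-fit chi-square p-values, Basal Eurasian proxy
    proportion estimation with delta-method composition of predictions,
    principal-component projection of missing-data samples, sample-level
    quality control (coverage-based genetic sexing, pairwise mismatch
    rates), text EIGENSTRAT input/output with pseudo-haploid calling and
    dataset merging, and an admixture-graph allele-frequency simulator
    (Balding-Nichols drift, pseudo-haploid sampling, coverage-driven
    missingness) so the whole inference stack can be validated at desk
    scale.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
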