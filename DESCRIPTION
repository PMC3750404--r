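Package: dualtheta
Title: Watterson's Theta from Error-Prone Pooled Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators of Watterson's theta (per-site nucleotide
    diversity) from next-generation sequencing data with appreciable
    sequencing error: a single-line estimator that samples one haploid
    genome per diploid individual, a pooled-sample single-platform
    estimator that corrects for binomial read sampling of alleles, and a
    pooled-sample dual-sequencing-application estimator that exploits the
    non-overlapping error distributions of two independent sequencing
    runs to separate rare polymorphisms from errors.  Includes read-count
    truncation (removal of singleton and doubleton read classes), the
    allele-detection probability theory used to debias the estimates, a
    forward simulator of polymorphic regions under the neutral
    infinite-sites model with Poisson coverage and constant or
    Beta-distributed per-site error rates, a minor-allele-frequency
    screen for error-dominated sites, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
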