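Package: trioseg
Title: Trio Whole-Exome Segregation Analysis, Variant Prioritization and
    Autozygosity Estimation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for case-parent trio whole-exome studies: genotype-level
    filtering on allele balance and genotype quality, pedigree-informed
    genotype posteriors with a mutation-aware transmission prior, per-trio
    segregation classification (de novo, homozygous recessive, and
    transmission-phased compound heterozygotes), cross-family recurrence,
    minor-allele-frequency and in-silico pathogenicity prioritization with
    rank-sum score comparison and hypergeometric gene-set
    over-representation, maximum-likelihood hidden-Markov-model estimation
    of the inbreeding coefficient with a boundary likelihood-ratio test,
    and a fully seeded synthetic trio-exome generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
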