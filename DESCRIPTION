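Package: diplotyper
Title: Phased Multi-Allelic Gene Allele Prediction from Flanking SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Treats the phased intragenic SNP sequence of a gene as one level
    of a multi-allelic polymorphism and predicts the pair of gene alleles
    (the diplotype) a subject carries from unphased genotypes of flanking tag
    SNPs. Provides EM estimation of haplotype frequencies from unphased
    genotypes under Hardy-Weinberg equilibrium, posterior diplotype calling
    with a confidence threshold, AIC-penalized forward-backward selection of
    informative tag SNPs within a flanking window, Bayesian prediction of
    gene alleles for new subjects with call thresholds, Shannon-entropy
    polymorphism summaries, expected-dosage multi-allelic case-control
    association, translation of coding gene alleles to amino-acid alleles,
    and simulators that generate cohorts with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
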