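Package: KernelPred
Title: Multi-Kernel Genomic Prediction from SNPs, Haplotype Blocks and
    Runs of Homozygosity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds SNP, haplotype-block and runs-of-homozygosity (ROH)
    feature matrices from PLINK-format genotypes, constructs linear and
    Gaussian genomic relationship kernels, fits single- and multi-kernel
    Bayesian mixed models by Gibbs sampling, and evaluates phenotypic
    prediction by k-fold cross-validation with variance partitioning
    across kernels.  Includes a forward simulator of half-sib/inbred
    cattle-like populations (block-wise linkage disequilibrium, ROH from
    inbreeding loops, herd-year-season and age fixed effects) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
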