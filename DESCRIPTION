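Package: graftnoise
Title: Statistical Audit of SNP-Based Evidence for Graft-Mobile mRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for auditing single-nucleotide-polymorphism (SNP) based
    claims of graft-mobile messenger RNAs from bulk RNA-seq of grafted
    plants. Implements a cumulative-binomial false-positive model for
    published read-count mobility criteria, homograft-based background
    error-rate estimation, a conjugate beta-binomial Bayes-factor
    comparison of sequencing noise against a genuine foreign-genotype
    component, read-level co-occurring-SNP consistency classification,
    comparisons of allele-fraction distributions at SNP versus
    neighbouring positions, contamination diagnostics by source-tissue
    expression regression, and pseudo-heterozygosity flagging. A
    truth-labelled synthetic graft-experiment generator reproduces the
    statistical structure these analyses assume, so every stage can be
    exercised and calibrated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
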