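Package: snpanchor
Title: Reducing Allele-Dropout False Negatives in Single-Cell Variant Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calling variants from single-cell DNA sequencing data
    while controlling the false negatives caused by allele dropout (ADO)
    during whole-genome amplification. Implements a Bayesian pileup genotype
    caller over the ten diploid genotypes with a GC-biased base-error model
    and a strict posterior-dominance calling rule; a linked-SNP strategy that
    anchors each candidate site to a heterozygous germline SNP within one
    read length, so that absence of a mutant allele can be promoted to a
    confirmed wild-type only when the anchor proves both haplotypes
    amplified; somatic-mutation identification filters (QUAL/FS/QD/GQ, depth
    gates, germline-SNP exclusion, bulk concordance, binomial multi-cell
    support); a self-validation error-rate estimator based on heterozygous
    SNP pairs; per-cell false-negative-rate estimation; a ternary
    cells-by-sites genotype matrix; a detector for mutation patterns
    incompatible with clonal tumor growth; and a seeded simulator of
    amplification dropout and sequencing error for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
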