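Package: ncdscan
Title: Genome Scans for Long-Term Balancing Selection with the
    Non-Central Deviation Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects long-term balancing selection from population
    genomic data with the Non-Central Deviation statistics NCD1 and
    NCD2, folded site-frequency-spectrum summaries that quantify how
    close minor allele frequencies lie to a hypothesized balanced-allele
    target frequency, optionally counting fixed differences to an
    outgroup as informative sites at frequency zero.  Provides the full
    sliding-window scan procedure (window filtering on informative-site
    and outgroup-orthology content, significance against
    informative-site-matched neutral coalescent simulations,
    Z-standardization, empirical-P outlier calling and target-frequency
    assignment), readers for VCF genotypes, outgroup FASTA, BED masks
    and ms-format simulation output, coalescent and forward
    Wright-Fisher simulators with an overdominant balanced polymorphism
    and an outgroup lineage, and a power-evaluation harness (ROC and
    true-positive rate at fixed false-positive rate) including Tajima's
    D and an HKA-type polymorphism/divergence test as comparators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
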