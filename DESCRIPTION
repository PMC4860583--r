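Package: amplidup
Title: Duplicate Provenance, Amplification Bias and Power in RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how PCR amplification and read-duplicate removal
    affect RNA-seq quantification. Provides a protocol-aware synthetic read
    generator (TruSeq-, Smart-Seq- and UMI-seq-like libraries with
    duplicate-provenance truth labels), single-end, paired-end and UMI
    duplicate detection, an occupancy model for the fraction of duplicates
    expected from sampling alone together with a fragmentation-bias fit,
    fragmentation-profile analyses (5' start profiles, GC covariates and
    transposase position weight matrices), spike-in accuracy fits of TPM
    against known molarities under different duplicate treatments, and
    negative-binomial power and false-discovery-rate simulations for
    differential expression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Rcpp,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    MASS,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
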