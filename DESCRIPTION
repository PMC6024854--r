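Package: introgressr
Title: SNP-Typing and Introgression Profiling for Early-Backcross Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genotyping-by-sequencing SNP-typing pipeline for early-backcross
    introgression-line panels (e.g. rice BC1F5 populations): read-support
    genotype calling from per-site allele depths, a site filter cascade ending
    in a low-missing-data (LMD50) SNP set, parent-based introgression
    profiling with sliding-window allele-frequency scans and selective-sweep
    flagging, synonymous/non-synonymous annotation with SIFT-score
    classification, and neighbor-joining diversity analysis. Includes a
    breeding-design simulator (single backcross followed by selfing, optional
    selection at target loci, negative-binomial read depths) used as the test
    bed for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
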