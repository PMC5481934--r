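Package: mbdpipe
Title: Methylome Profiling and Methylation-Expression Integration for
    MBD-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for characterizing an MBD-seq methylome and
    integrating it with expression data: peak annotation with per-region and
    per-chromosome density normalizations, metagene coverage profiles, CpG
    island detection by sliding-window criteria (length, GC content,
    observed/expected CpG), methylation calling on CpG islands by peak
    coverage, replicate-based differential methylation with gene-level
    aggregation, and a jackknife resampling test for the enrichment of
    differentially methylated genes among differentially expressed genes.
    Ships a synthetic-data generator with planted ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
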