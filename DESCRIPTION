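Package: ctsplice
Title: Co-Transcriptional Splicing Analysis for Chromatin-Bound RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies co-transcriptional splicing from chromatin-bound RNA
    sequencing (CB-RNA-seq) of plants and other eukaryotes. Computes per-intron
    5' and 3' splice-site ratios (coverage of the first/last intronic base over
    the adjacent exonic base, an estimate of the unspliced fraction at each
    junction), aggregates them to gene level under an FPKM expression filter,
    stratifies by intron order and intron number, and builds TPM-scaled metagene
    coverage profiles over scaled gene bodies (TSS to PAS). Includes a
    mechanistic simulator of the three chromatin RNA populations - elongating
    transcripts truncated at the polymerase position (RNAe), polyadenylated but
    incompletely spliced chromatin RNA (RNAf), and mature mRNA - that emits
    aligned reads with exact per-junction ground truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
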