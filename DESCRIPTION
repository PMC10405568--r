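Package: circsis
Title: Identification and Characterization of Circular Stable Intronic Sequence RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A post-caller analysis pipeline for circular stable intronic
    sequence RNAs (sisRNAs) from total RNA-Seq junction calls: extraction of a
    unique non-exon-overlapping intron universe from a GTF annotation, host
    intron assignment, collapsing of same-5'-splice-site circular junctions
    into clusters, classification of clusters as stable lariats or full-length
    intronic circles, branch point assignment and 3' tail analysis, sequence
    context windows with information content and IUPAC motif scanning,
    per-base read-depth and conservation profiles, RPM/FPKM expression
    normalization, RNase R enrichment testing, and cohort-level statistics
    (tissue specificity, cell-fraction localization, risk-class differential
    expression, Kaplan-Meier survival). Includes a synthetic-data generator
    with ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    survival,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
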