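Package: isoforge
Title: Structural Annotation of Full-Length Transcript Isoforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structural annotation of full-length (Iso-Seq style)
    transcript isoforms against a reference genome and annotation: retention
    filtering of aligned full-length non-chimeric (FLNC) reads, redundancy
    collapse, grouping of isoforms into gene loci, three-way novelty
    classification (known isoform, novel isoform of a known gene, novel
    locus), fusion-transcript calling from multi-segment alignments,
    alternative-splicing event typing (SKIP/MSKIP, IR/MIR, AE and their
    approximate X variants), splice-site dinucleotide census, splice-junction
    genomic-context assignment, polyadenylation-site clustering with
    alternative-polyadenylation calling, and merging of novel isoforms with a
    reference annotation into a unified transcript library. Includes a
    deterministic synthetic-data generator (toy genomes, annotations, FLNC
    alignments, junction support, ground truth) so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
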