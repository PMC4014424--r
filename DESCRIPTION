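Package: nrpeaks
Title: Nuclear-Receptor ChIP-Seq Peak Annotation, Repeat-Element Motif
    Scanning and Knockdown Integration
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates transcription-factor ChIP-seq peaks against gene
    models by nearest transcription start site and a promoter/distal/gene
    desert taxonomy, scans peak-center windows for nuclear-receptor
    direct/everted/inverted repeat elements (DR/ER/IR with 0-8 spacer
    nucleotides) with a consensus-with-mismatches grammar, integrates
    shRNA-knockdown RNA-seq expression tables through double fold-change
    and FPKM cutoffs, profiles per-base conservation scores around peak
    centers with GC- and length-matched random genomic backgrounds, and
    counts co-localization of distal peaks with enhancer chromatin marks.
    A seeded synthetic-data generator produces complete ground-truthed
    input bundles (genome, gene models, peaks with planted region classes
    and motifs, conservation track, expression tables, mark intervals) so
    every stage is testable end to end with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
biocViews: ChIPSeq, RNASeq, Annotation, MotifAnnotation, Coverage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
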