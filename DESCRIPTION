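Package: rremine
Title: RRE-Guided Genome Mining of RiPP Precursor Peptide Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Class-independent genome mining for ribosomally synthesized and
    post-translationally modified peptides (RiPPs) guided by the RiPP
    Recognition Element (RRE). Builds bitscore-thresholded similarity graphs
    from all-by-all BLAST/DIAMOND tabular hits, clusters RRE-containing
    enzymes into single-linkage families, harvests short open reading frames
    from gene neighborhoods around each anchor, and recursively pairs enzyme
    families with co-occurring precursor-peptide families at escalating
    bitscore thresholds. Includes a position-frequency profile of precursor
    candidates, an elemental mass ledger for the threonine-to-Dmp
    (N2,N2-dimethyl-1,2-propanediamine) modification pathway, a deterministic
    synthetic-genome generator with planted family structure for recovery
    testing, and an end-to-end mining pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
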