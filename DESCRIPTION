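Package: islandseq
Title: Detection and Characterisation of Transgene Integration Islands from
    Noisy Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates and characterises transgene integration islands in
    transgenic nuclear genomes from noisy long sequencing reads, and verifies
    non-integration of episomes. Reads are aligned to the delivered construct
    and the host reference with an internal k-mer seed-and-chain mapper (or
    ingested from PAF/BLAST tabular alignments), false-positive construct hits
    arising from promoter/terminator segments shared with the host genome are
    masked out, and every read is classified as genome-only, construct-only,
    left/right border, spanning, false positive or ambiguous. Border anchors
    are clustered into integration islands with resolved insertion sites,
    exact or minimum island sizes, reconstructed sense/antisense concatemer
    structure, and nearby genomic feature context. Includes coverage
    arithmetic (Clarke-Carbon coverage probability, read-budget estimation of
    unresolved island size, full plasmid-copy equivalents), a fluorescence
    screening summariser, and a synthetic-data generator producing host
    genomes, constructs, concatemer islands, episome pools and noisy
    log-normal-length long reads with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
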