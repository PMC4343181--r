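Package: apamap
Title: PolyA-Site Mapping and Tissue-Specific 3'UTR Isoform Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps polyadenylation (polyA) sites from 3'-end-tagged RNA-seq
    reads, filters internal-priming artifacts, clusters cleavage positions
    into polyadenylation-site (PAS) clusters and attaches them to genes,
    quantifies union-exon FPKM expression, builds per-tissue 3'UTR isoform
    catalogs, classifies tissue-specific alternative-polyadenylation (APA)
    switches, profiles PAS hexamers and cleavage-site nucleotide context,
    scans promoter regions for positionally enriched hexamers, and tests
    APA-switching gene sets for microRNA-target enrichment against
    size-matched random gene draws. Ships a seeded synthetic-data generator
    (toy genome, annotation, per-tissue polyA+ reads and ground-truth
    tables) so every pipeline stage is verifiable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
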