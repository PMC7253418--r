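Package: isoatlas
Title: Transcript Classification, Validation and Alternative Splicing
    Analysis for Long-Read Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Augments a reference gene annotation with transcript models
    assembled from long-read sequencing across developmental stages.
    Classifies assembled transcripts against the reference by exon-chain
    comparison (exact match, contained, novel isoform, novel gene, other),
    merges stage transcriptomes, validates novel transcripts by coding
    potential, sequence conservation against length-matched intergenic
    controls, promoter H3K4me3 chromatin signal and CAGE support,
    enumerates seven types of alternative-splicing events with PSI and
    permutation-based differential splicing, and calls zygotic genome
    activation (ZGA) transcripts from stage expression matrices. Ships a
    fully self-consistent synthetic data generator with known ground
    truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
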