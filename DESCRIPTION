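Package: mirseed
Title: Seed-Match miRNA Target Discovery from Expression Profiles
Version: 0.1.0
Authors@R:
    person("mirseed", "developers", email = "mirseed@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for discovering candidate microRNA targets
    from transcriptome profiling experiments. Provides exact seed-match
    scanning of 3'UTR sequences (6mer/8mer Watson-Crick sites), quantile
    normalization and moderated-t differential expression with
    Benjamini-Hochberg control, hypergeometric over-representation of
    predicted targets among up- and down-regulated transcripts, weighted
    running-sum (GSEA-style) signature enrichment with permutation
    significance, multi-evidence candidate filtering with cross-species
    support, and cross-model miRNA overlap analysis. Includes synthetic-data
    generators with planted ground truth so the whole pipeline is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
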