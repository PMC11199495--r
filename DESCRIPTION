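Package: digestax
Title: Reference Database Expansion and Community Profiling for Anaerobic
    Digester 16S rRNA Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ecosystem-specific 16S rRNA gene reference databases
    and amplicon surveys of anaerobic digesters. Expands a full-length 16S
    reference database with new amplicon sequence variants: end-gap-free
    pairwise identity, nearest-neighbour search, deduplicating merge,
    per-rank sequence-novelty classification against Yarza identity
    thresholds, and deterministic placeholder taxonomy (midas_<rank>_<n>)
    for lineages without official names. Evaluates short-read ASV sets
    against a database (rare-biosphere filtering, high-identity coverage,
    k-mer bootstrap classification and per-sample classification rates),
    scores PCR primer pairs in silico with 3'-weighted mismatch penalties,
    classifies taxa into strict/general/loose core and conditionally rare
    or abundant taxa (CRAT) per metadata group, and provides diversity
    statistics (rarefaction, inverse Simpson, Bray-Curtis, PCoA,
    permutation PERMANOVA). Includes seeded synthetic-data generators with
    planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
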