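Package: ghArch
Title: Domain Architectures of Glycoside Hydrolases in Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs per-protein domain architectures of bacterial
    cellulases, xylanases and chitinases from HMMER3 Pfam scans
    (domtblout tables). Applies significance and profile-coverage
    filters, resolves overlapping hits, classifies proteins as
    single-domain, multi-domain (MDGH) or multi-activity (MAGH)
    glycoside hydrolases, profiles per-genome GH content, and
    quantifies the taxonomic conservatism of protein architecture
    versus GH family content with hierarchical clustering and
    permutation Mantel tests. Includes a fully ground-truthed
    synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
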