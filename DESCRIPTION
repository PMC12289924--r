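Package: micoexpress
Title: Gene Co-Expression Ecology for Paired Metagenomes and Metatranscriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing microbial community gene expression from paired
    metagenomic (MG) and metatranscriptomic (MT) gene-level counts. Normalizes
    counts to TPM and forms the MT/MG ratio as a proxy of microbial
    transcriptional activity (MTA), builds a signed weighted co-expression
    network with topological overlap, dynamic tree cut and eigengene merging,
    associates modules with sample traits, selects hub genes, and computes
    community-ecology statistics of gene expression: module diversity,
    taxonomic diversity of gene expression (tDGE) and functional redundancy
    via Rao quadratic entropy. Includes rank-based differential activity
    analysis, preranked gene-set enrichment with a permutation null,
    cross-feeding correlation analysis, and a synthetic-data generator with
    planted modules, group effects and taxon dropout for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    withr
Config/testthat/edition: 3
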