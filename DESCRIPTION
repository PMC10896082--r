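Package: holotarget
Title: Gene Target Discovery for Sap-Feeding Insect Pests from Tissue
    Enrichment, Motif Filters and Host-Symbiont Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline that nominates RNA-interference gene
    targets in phloem-feeding insects such as the cassava whitefly
    (Bemisia tabaci SSA1-SG1).  It screens gene-level RNA-seq count
    matrices for gut- and bacteriocyte-enriched transcripts (TMM
    normalisation, negative-binomial likelihood-ratio tests,
    Benjamini-Hochberg FDR), applies rule-based protein filters for
    osmoregulation candidates (glycoside hydrolase family 13 sucrases
    with an intact catalytic dyad and signal peptide; water-specific
    aquaporins with dual NPA boxes and an F/H/A/R ar/R constriction),
    and builds a two-compartment host-endosymbiont genome-scale
    metabolic model analysed by flux balance analysis, flux variability
    analysis, single gene and reaction deletion, MOMA and ROOM to
    identify essential symbiosis genes.  A synthetic-data module
    generates seeded count matrices, motif-bearing protein sets and a
    curated toy holobiont network with known essentiality answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    edgeR,
    jsonlite,
    quadprog,
    stats,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
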