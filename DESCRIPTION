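Package: ptmpath
Title: Projection of PTM Perturbation Data onto Pathway Diagrams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalizes KEGG (KGML) and WikiPathways (GPML) pathway diagrams
    into a unified pathway-skeleton graph with JSON serialization, projects
    regulated post-translational modification (PTM) datasets onto those
    graphs with deterministic force layout and static SVG export, and scores
    datasets with a battery of enrichment methods: gene-centric and
    gene-centric-redundant set enrichment using an ECDF-difference statistic,
    PTM-signature enrichment with signed site sets, kinase-substrate
    enrichment analysis (KSEA), and kinase motif enrichment based on
    position-specific scoring matrices with Fisher tests. Includes readers
    for PTM regulation tables and dose-response (CurveCurator-style) outputs
    and a deterministic synthetic-fixture generator for pathways, datasets,
    signatures and kinase annotation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
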