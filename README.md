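# ptmpath

Phosphoproteomic (and other PTM) perturbation experiments produce lists of
regulated modified peptides, but the biological question is almost always a
pathway-level one: *where in the signaling network did the drug or stimulus
act?* `ptmpath` answers it at the desk: it normalizes canonical pathway
diagrams from the two major public databases into a single graph
representation, projects regulated PTM peptides onto the proteins of those
diagrams as a static, publication-ready SVG, and scores the dataset with a
battery of kinase- and pathway-enrichment methods so that candidate diagrams
can be ranked and perturbed kinases flagged directly in the picture.

It is aimed at computational proteomics groups who have already done the
differential or dose-response analysis (limma/Perseus t-tests, or
dose-response curve fitting with pEC50 and curve fold change per peptide)
and now need the pathway-context step to be scriptable, hermetic (no network
access) and reproducible.

## What it does

**Pathway normalization.** KEGG KGML and WikiPathways GPML files are parsed
into a common *pathway skeleton*: a mixed graph with typed nodes
(`gene_protein`, `compound`, `pathway`, `misc`, `group`), typed edges that
may terminate on other edges, and the original diagram coordinates. KGML
`gene`/`ortholog` entries collapse to `gene_protein`, many-to-many reactions
are expanded into one edge per substrate–product pair, and the two
documented subtype merges are applied (`repression`→`inhibition`,
`indirect effect`→`indirect`). GPML's 13 node kinds map onto the four
unified types, 10 of its 24 arrowhead edge types map onto the KEGG-derived
vocabulary (14 are retained), and anchor constructs become edges whose
endpoint is another edge. Identifier unification (KEGG/Entrez/Ensembl →
UniProt → gene symbol) runs through offline two-stage mapping tables.
Pathways with no gene-product node are reported as skipped. Skeletons
serialize to a versioned JSON schema with a lossless round-trip.

**Projection and rendering.** Records match skeleton nodes by UniProt
accession (isoform-stripped) and/or gene symbol; a protein drawn twice gets
two PTM nodes. PTM nodes are colored by regulation (up = red, down = blue,
not = gray), by log2 fold change, or by potency (pEC50), with the continuous
domain fixed over the matched records. A deterministic force layout (springs
toward the reference node, inverse-square repulsion among siblings,
backtracking descent, a collision-radius guarantee) places PTM nodes, and
the renderer emits SVG with the four visual edge classes, convex-hull group
polygons, kinase–substrate overlay arrows and activity highlight rings.

**Enrichment battery.** Four methods whose statistic is computed here:

- *Gene-centric / gene-centric-redundant set enrichment.* The score is the
  normalized integrated ECDF difference over ranked profile positions,
  `score = (1/N) Σᵢ [F_sig(i) − F_rest(i)]`; gene-centric collapses
  duplicate keys to the max-|value| entry, the redundant flavor counts a
  gene once per regulated peptide. Permutation p-values use size-matched
  random member sets, `p = (1+k)/(1+n_perm)`, BH-adjusted per experiment.
  PTM-site signatures with signed members (±1) are supported by negating
  the values of −1-signed members before ranking.
- *KSEA.* Per kinase with `m` annotated substrates,
  `z = (mean_substrates − mean_all)·√m / sd_all`, two-sided normal p, BH
  across kinases.
- *Kinase motif enrichment.* Peptide flanking windows (−5..+4) are scored
  against per-kinase PSSMs (sum of log2 weights), converted to background
  percentiles, the top-15 kinases per site are kept, and each kinase is
  tested per regulation direction with a two-sided Fisher exact test, BH
  across kinases.
- *Pathway ranking* orders candidate diagrams by |gene-centric-redundant
  score|.

**Data ingestion.** CSV regulation tables (sniffed delimiter, site strings
like `S1134` split into residue + position, malformed rows collected with
line numbers), dose-response curve tables with their TOML parameter file
(potency kept only for regulated curves, pEC50 checked against the dose
window), and the four-rule deduplication for two-dose screens (keep the most
significant entry per peptide within an experiment, then prefer the
significant high-dose entry, else the significant low-dose entry, else the
high-dose entry).

**Synthetic fixtures.** `synthetic_spec()` + `make_fixture_pathway()` /
`make_synthetic_dataset()` / `make_fixture_pssms()` generate seed-stable
KGML/GPML documents with ground-truth skeletons and PTM datasets with
planted kinase signal, so everything above is testable offline.

## Worked example

```r
library(ptmpath)

spec     <- synthetic_spec(seed = 42)          # study conditions
fx       <- make_fixture_pathway(spec, "kgml") # synthetic KGML + ground truth
skeleton <- parse_kgml(fx$xml, fx$id_map)
skeleton
#> <pathway_skeleton> syn00042 (Synthetic pathway syn00042, kegg)
#>   13 nodes (compound: 2, gene_protein: 9, group: 1, pathway: 1), 15 edges

ks      <- make_fixture_ks_table(spec)                  # kinase annotations
dataset <- make_synthetic_dataset(spec, ks_table = ks)  # planted KIN1 inhibition
graph   <- project_dataset(dataset[dataset$regulation != "not", ], skeleton)
graph
#> <projected_graph> on syn00042
#>   4 PTM nodes, 0 summary nodes, 4 anchor edges, 0 overlay edges,
#>   0 highlights, 55 unmatched records

fc <- data.frame(id   = vapply(dataset$gene_names, `[`, "", 1),
                 site = vapply(dataset$sites,
                               function(s) paste0(s$residue[1], s$position[1]), ""),
                 value = dataset$fold_change)
head(ksea(fc, ks), 3)
#>   kinase   z_score            p        p_adj n_substrates
#> 1   KIN1 -7.318550 2.506651e-13 5.013303e-12           10
#> 2  KIN13  1.028584 3.036750e-01 9.918386e-01           10
#> 3  KIN15  0.994010 3.202180e-01 9.918386e-01           10

graph <- layout_ptm_nodes(graph, layout_params(seed = 1))
write_svg(render_svg(graph, show_site_labels = TRUE), "figure.svg")
```

The KSEA table reads: the planted kinase KIN1 has strongly decreased
inferred activity (z = −7.3 from its 10 annotated substrates, BH-adjusted
p ≈ 5×10⁻¹²), while every other kinase stays at background (|z| ≈ 1,
adjusted p ≈ 1). The 55 unmatched records are regulated peptides whose
genes are not drawn in this 9-protein diagram — exactly the kind of
information the projection is meant to surface.

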