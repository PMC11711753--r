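---
title: "Projecting PTM perturbation data onto pathway diagrams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting PTM perturbation data onto pathway diagrams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmpath)
```

This vignette documents the models, conventions and numerical choices behind
`ptmpath`: how heterogeneous pathway XML dialects are reduced to one graph
model, how PTM datasets are projected and drawn, what each enrichment
statistic assumes, and which decisions were genuinely open and how they were
fixed. It states no result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## The pathway skeleton model

Both KEGG (KGML) and WikiPathways (GPML) describe a pathway as a mixed graph
of *regular nodes* — typed, labeled, with 2-D cartesian pixel coordinates
(origin top-left, y growing downward, following both source formats) — and
*group nodes* defined only by their member set. `ptmpath` normalizes both
dialects into one `pathway_skeleton`: five node types (`gene_protein`,
`compound`, `pathway`, `misc`, `group`), edges carrying a *set* of relation
subtypes, and endpoint references that may name an edge instead of a node
(the normal form of GPML anchors). Diagrams without a single `gene_protein`
node are reported as *skipped* rather than imported: they cannot carry PTM
projections and are typically pure metabolite maps.

Skeletons serialize to JSON with top-level keys `formatVersion`,
`pathwayId`, `name`, `organism`, `sourceDb`, `nodes`, `edges`. The field
names and schema are artifact-defined (neither source database publishes a
JSON schema for this purpose); the schema is versioned so it can evolve.
Coordinates are stored and written at 2-decimal precision, which is what
makes `load(save(x))` an identity — the test suite checks the double
round-trip byte-for-byte.

### Mapping tables

Three vocabularies drive normalization; all three ship as code
(`kegg_relation_subtypes()`, `gpml_node_types()`, `gpml_edge_types()`) so
conformance is testable:

* **KGML relation subtypes.** 19 entries mapping onto 17 unified subtypes
  through exactly two merges (`repression` into `inhibition`,
  `indirect effect` into `indirect`). The core of the list is the published
  KGML vocabulary; the final entries (`indirect`, `demethylation`,
  `sumoylation`) cover subtype spellings observed in the wild and make the
  19→17 structure explicit. The table is artifact-defined in that sense.
* **GPML node kinds.** 13 entries (the DataNode `Type` values plus `Label`
  and `Shape` elements) mapping onto `gene_protein`, `compound`, `pathway`
  and a catch-all `misc`. `Complex` maps to `misc` rather than to a group:
  GPML complexes are single drawn nodes, while skeleton groups require
  member nodes.
* **GPML edge types.** 24 arrowhead values; 10 are converted to
  KEGG-derived subtypes (activation-like arrowheads to `activation`,
  T-bar/inhibition arrowheads to `inhibition`, binding arrowheads to
  `binding/association`, transcription–translation to `expression`) and 14
  are retained verbatim. Which specific arrowheads belong to the mapped set
  is artifact-defined; the counts are the documented conformance surface.

Unknown inputs never abort an import: an unknown node kind becomes `misc`,
an unknown edge subtype is retained verbatim, both with a warning.

### Edges, reactions, anchors

KGML *reactions* are many-to-many; the skeleton represents only one-to-one
edges, so each reaction is expanded into |substrates| × |products| directed
substrate→product edges. A *reversible* reaction is recorded as a
`reversible` marker in the relation-type set of each expanded edge rather
than as a duplicated back-edge — the graph stays smaller and no information
is lost (renderers or analyses that care can branch on the marker).

GPML *anchors* (an interaction terminating on a point along another
interaction) are resolved by replacing the anchor reference with the id of
the interaction that owns the anchor. After resolution no anchor constructs
remain, every endpoint reference resolves, and chains (an anchored edge that
itself ends on an edge) are handled transitively.

Four visual edge classes exist (`activation`, `inhibition`,
`binding_association`, `indirect`); every other subtype renders in one
common style. Because an edge carries a *set* of subtypes, a tie rule is
needed and is fixed as inhibition > activation > indirect >
binding_association > other — inhibition is the most consequential signal
to lose visually, so it wins.

### Identifier mapping

All identifier unification is offline: two-stage lookup tables
((database, id) → UniProt accession → gene symbol) loaded from TSV. Lookups
are total — a missing key yields an empty annotation, never an error or a
network call. For GPML xrefs, a UniProt xref is taken at face value;
otherwise Entrez, Ensembl and HGNC xrefs go through the table. Multi-id
KGML entries (one entry naming several genes) become one node carrying all
mapped accessions and symbols, labeled by the first mapped symbol — this
maximizes human-readable labels without inventing extra nodes.

## Projection

A record matches a node if any isoform-stripped accession matches exactly
*or* any gene symbol matches case-insensitively (union semantics; the
precedence order is irrelevant to the outcome, only to short-circuiting). A
record matching several nodes yields several PTM nodes — proteins
legitimately appear more than once in canonical diagrams. Unmatched records
are returned, not dropped: the unmatched count is itself informative (how
much of the regulation lies outside the chosen diagram).

With `collapse = TRUE`, per-record PTM nodes are replaced by one summary
node per (protein, regulation type) labeled with the count, the compact view
for dense datasets.

Three color scales: `regulation` (fixed palette: up `#d62728`, down
`#1f77b4`, not `#999999`), `fold_change`, and `potency` (pEC50, the −log10
molar half-effective concentration; higher = more potent). Continuous
domains are fixed *after* matching, over matched records only, so the full
gradient is spent on what is actually drawn; the domain endpoints map
exactly onto the endpoint colors. Two edge cases are fixed deliberately: a
degenerate domain (all matched values equal) yields the midpoint color, and
a matched record lacking the scaled value renders in a designated no-value
gray rather than being dropped.

Kinase–substrate overlay edges are added for annotation rows whose kinase
matches a `gene_protein` node and whose substrate site — keyed as
(accession or gene symbol, residue letter, 1-based position), with
multiply-phosphorylated peptides matching on any site — matches a projected
PTM node. Kinase-activity highlights flag nodes whose kinase passes
|score| ≥ 0.5 (inclusive) and FDR < 0.1 (exclusive); those defaults mirror
common practice for calling a kinase perturbed from KSEA-type scores, and
the boundary semantics are part of the tested contract.

## Layout and rendering

PTM and summary nodes have no database coordinates; they are placed by
simulated forces: a spring toward the reference node (rest length 30 px ≈
node radius + margin, strength 0.05) and inverse-square repulsion (strength
400 px³) among floating nodes sharing a reference. Two properties were
prioritized over visual fidelity to any particular interactive force
engine:

1. **Determinism.** Initial angular positions come from integer hashing of
   the seed (no RNG state at all), and the optimizer is gradient descent
   with backtracking — a step is accepted only if the total potential does
   not increase. Two runs on the same input are bit-identical, and the
   energy trace is non-increasing by construction (both are asserted in the
   tests).
2. **A collision guarantee.** After descent, a deterministic pairwise
   separation pass enforces that no two floating nodes sharing a reference
   are closer than the collision radius (default 18 px, tolerance 1e-6).

The iteration budget is fixed (300); there is no convergence test, which
keeps runtime flat and reproducible.

The SVG renderer draws group nodes as polygons around the convex hull of
their members' corner rectangles (`grDevices::chull`; tests compare against
a brute-force hull oracle), gives the four visual edge classes distinct
dash/marker styles from a fixed style table (the style strings are part of
the test surface), omits the invisible PTM anchor edges, and derives every
element id from the graph ids so output is stable and diffable. Edges whose
endpoint is another edge are drawn to that edge's midpoint.

## Enrichment statistics

**ECDF-difference set enrichment.** For a profile of N entries ranked by
value (descending, stable ties), the score of a signature is
$\frac{1}{N}\sum_{i=1}^{N}\left[F_{sig}(i) - F_{rest}(i)\right]$, the
normalized integrated difference between the ECDF of member positions and
the ECDF of the remaining positions. Positive means members concentrate at
the top. The integrated (area) form is the default; the maximum-deviation
(KS) form is available via `statistic = "ks"`. Gene-centric profiles
collapse duplicate keys to the maximum-|value| entry; gene-centric-redundant
profiles keep every row, so a gene contributes once per regulated peptide.
The two coincide exactly on duplicate-free profiles (tested). Signed PTM
signatures negate the profile values of −1-signed members before re-ranking
— a site expected to go *down* under a perturbation then contributes
positively when it does. Zero overlap and whole-profile coverage yield `NA`
scores with diagnostics, not errors.

**Permutation p-values.** The reference implementations of this statistic
do not publish a closed-form null, so the null is permutational and
artifact-defined: size-matched member sets drawn uniformly without
replacement from the profile rows, `p = (1 + k)/(1 + n_perm)` with `k` the
number of permutations reaching the observed |score| (two-sided), BH across
the signatures of one experiment, deterministic under a seed. `n_perm`
defaults to 1000 (resolution ~0.001); the type-I error at α = 0.05 is
checked by simulation against the binomial confidence band. One subtlety:
because the statistic is symmetric, the bottom-k member set exactly ties the
top-k |score|, so the minimal p `1/(1+n_perm)` is attained only when no
permutation samples either extreme — a measure-zero event on realistically
sized profiles but a certainty on toy ones.

**KSEA.** The mean-fold-change z statistic:
$z = (\bar{x}_{sub} - \bar{x}_{all})\,\sqrt{m}\,/\,s_{all}$ for a kinase
with m matched substrate sites, two-sided normal p, BH across kinases,
kinases below `min_substrates = 3` omitted. Sites are deduplicated to the
max-|value| entry first. The statistic assumes sites are roughly independent
and the background roughly symmetric; a zero-variance background is a hard
error. With all sites as the substrate set, z is 0 by construction (tested).

**Motif enrichment.** Kinase PSSMs over the window −5..+4 around the
phospho-acceptor (the common kinase-motif convention; width configurable
through the PSSM object). A peptide's score against a kinase is the sum of
log2 preference weights at each position; padding (`_` or residues absent
from the matrix) is skipped; a wrongly sized sequence is rejected with its
index. Scores are converted to percentiles of a per-kinase background
distribution (fraction of background ≤ score), the top 15 kinases per site
are kept (stable tie-break by kinase order), and each kinase is tested per
regulation direction with a two-sided Fisher exact test on
(regulated vs not) × (in top-k vs not), BH across kinases within the
direction. The Fisher p is verified against an exhaustive hypergeometric
tail enumeration in the tests.

**BH adjustment** is the standard step-up procedure (via `stats::p.adjust`)
with input validation; it never decreases a p-value and is order-preserving.
Note that step-up BH is *not* idempotent on arbitrary already-adjusted
vectors — (0.01, 0.5) adjusts to (0.02, 0.5), which re-adjusts to
(0.04, 0.5) — only on constant plateaus where the minimum binds; the tests
assert the property that actually holds.

**Pathway ranking** sorts candidate diagrams by decreasing |score| of the
gene-centric-redundant analysis, NA-scored pathways last, stable ties. The
redundant flavor is the sort key because it rewards pathways with many
regulated peptides on few proteins — the diagrams worth looking at first.

## Data ingestion conventions

CSV columns are resolved through a documented, fully overridable column map;
the delimiter is sniffed among comma/tab/semicolon and the decimal separator
is fixed to `.`. Site strings (`S1134`, `T246;S250`) are split into residue
and 1-based position within the UniProt canonical sequence. Rows with an
unknown regulation vocabulary or malformed sites are collected into an error
report with their line numbers; a missing required column is a hard error.
None of the upstream tools' header conventions are normative here, hence the
column-map indirection with sensible defaults (`"Curve Regulation"`,
`"pEC50"`, `"Curve Fold Change"` for dose-response tables).

Dose-response ingestion keeps potency and effect size only for curves
classified regulated; a record's pEC50 outside the window implied by the
experiment's dose series (e.g. 1 nM–10 µM ⇒ pEC50 ∈ [5, 9]) is flagged in
its details, since such values are extrapolations of the curve fit. The TOML
reader is a deliberate subset (sections, scalars, flat arrays) sufficient
for dose-response parameter files, written in-package because no TOML parser
is part of the package's dependency footprint.

Two-dose screens are deduplicated per compound by four rules applied in
order: (I) within an experiment, keep a peptide's most significant entry
(lowest adjusted p — multiply-phosphorylated peptides produce duplicates);
then per peptide (III) a significant high-dose entry wins, else (IV) a
significant low-dose entry, else (II) the high-dose entry. Rules II–IV are
mutually exclusive and exhaustive over the four significance patterns,
which the tests sweep explicitly; the firing rule is recorded per output
row.

## The synthetic-fixture generator

The generator exists so every module is testable without downloads, and its
defaults are the package's study conditions, chosen once:

* pathway side: 12 regular nodes, 14 relations, one group, one
  many-to-many reaction (KGML) or one anchored interaction (GPML) — small
  enough to hand-check, structurally complete;
* dataset side: 500 peptides; the planted kinase's 10 annotated substrates
  shifted by −1.5 log2 units over Gaussian noise of sd 0.3 (a strong
  drug-sized effect over typical spread); 5% up- and 5% down-regulated
  bystander peptides at ±2 log2 — regulation not attributable to the
  planted kinase, as in real screens where one perturbation explains only
  part of the regulated proteome;
* potency mode assigns regulated records pEC50 values spanning exactly a
  band of 6.4–7.4, emulating a selective inhibitor acting within roughly
  one order of magnitude of concentration.

What the fixtures deliberately do **not** emulate: realistic
phosphoproteome depth (tens of thousands of sites), correlated substrates
(shared peptides between kinases, co-regulation), heavy-tailed fold-change
distributions, missing values, or the full breadth of real KGML/GPML files
(multi-compartment graphics, states, literature annotations). Passing tests
therefore demonstrate correctness of the algorithms under controlled
conditions — exact oracle agreement, calibration, planted-signal recovery —
not performance claims on real datasets.

Everything is deterministic under the spec seed; pathway fixtures are
byte-identical across runs, and ground-truth skeletons ship alongside the
XML so the readers are tested against structure, not byte layout.

## Problem sizes

The shipped tests and the acceptance script use: exhaustive
enrichment-oracle sweeps over profiles of ≤ 8 items and signatures of ≤ 3
members; 50 random KSEA closed-form instances (agreement to 1e-12); 100
seeded planted-recovery runs at 10/500 substrates; 500 null signatures ×
200 permutations for calibration; the exhaustive 2×2 Fisher sweep over all
tables with total count ≤ 30; 100 random skeleton round-trips; and 20-point
hull/layout checks. These sizes make the full suite run in about two
minutes while keeping every statistical check inside its nominal confidence
band.

## Known limitations

* GPML `State` elements (PTM decorations drawn on nodes) are ignored on
  import; projections are driven by the user's data, not by the diagram's
  own PTM annotations.
* The layout reproduces the *contract* (proximity, no collisions,
  determinism) of interactive force engines, not their exact visual output.
* Enrichment scores are comparable in sign and ordering with the reference
  single-sample GSEA implementations but are not numerically identical to
  any particular one (weighting exponents and normalization conventions
  differ across implementations and are not part of this package's
  contract).
* KSEA inherits the usual caveats of annotation-based activity inference:
  shared substrates between related kinases produce correlated scores.
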