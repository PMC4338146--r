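---
title: "Ordinal ISH annotation analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal ISH annotation analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ishannot)
```

## The data model

The central object is a gene-by-tissue grid of ordinal expression calls from
an *in situ* hybridization (ISH) screen. Each cell holds exactly one of five
mutually exclusive states: **not analyzed** (`na`, the signal could not be
determined reliably), **negative**, **weak**, **medium**, **strong**. The
reference setting is a late-gestation (E14.5) mouse screen of 2000 genes
over a 25-tissue ear/sensory panel (`T1`–`T25`), whose per-tissue state
counts ship with the package (`tissue_counts_table()`), but the tools are
generic over any panel.

Rank computations use the ordinal codes negative = 0, weak = 2, medium = 3,
strong = 4, with `na` masked out. The code gap between negative and weak is
the scoring convention of the source annotation system and is kept verbatim;
because every downstream statistic is rank-based, any strictly monotone
recoding yields identical correlations (this invariance is tested), so the
gap is cosmetic for the dendrogram while remaining faithful to the stored
scale. A gene is "expressed" in a tissue when its call is weak, medium or
strong; `na` is *never* silently folded into any level — it participates in
a query only when asked for explicitly, mirroring the separate bookkeeping
of not-analyzed cells in the summary table.

### Percentage rounding

Per-tissue percentages are reported to one decimal using IEEE
round-to-nearest applied to the double-precision ratio (the C `"%.1f"`
rule). This choice is empirical: among candidate rules (exact-decimal
half-to-even, R's `round()`, half-away-from-zero), only this one reproduces
every cell of the published 25-tissue count/percentage table, which the
acceptance checks verify for all 150 percentage cells.

## Sieve queries and gene-list algebra

Sieve queries are Boolean combinations of per-tissue predicates, written in
a small infix grammar: `T9 is expressed AND T22 in {medium,strong}`, with
`AND` binding tighter than `OR`, parentheses, and `expressed` as sugar for
`{weak,medium,strong}`. Negation is deliberately absent from the query
grammar; complementation is provided at the list level
(`combine_lists(..., "complement", universe = ...)`), so a query language
user can always realize NOT through the universe. Saved queries serialize
to JSON. Gene identifiers are matched case-insensitively everywhere, with
the first-seen spelling preserved for display.

## Tissue dendrogram

Tissue relationships are summarized by an unrooted distance tree:

1. **Correlation.** Spearman rank correlation between tissue columns of the
   ordinal encoding, with average ranks on ties (essential: the data are
   almost entirely ties) and pairwise-complete masking — for each tissue
   pair only genes analyzed in both enter. Pairwise deletion maximizes the
   usable data and matches the per-tissue accounting of `na` cells; a pair
   sharing fewer than three analyzed genes is an error, as is a tissue whose
   profile is constant within the shared gene set (the coefficient is
   undefined there).
2. **Distance.** `d = 1 - rho`, the standard correlation dissimilarity
   (identical profiles at 0, perfect reversal at 2). The transform is order
   preserving, so any monotone alternative would give the same neighbor
   ranking.
3. **Tree.** Canonical neighbor joining, authored in the package so that two
   determinism rules hold exactly: ties on the Q criterion resolve to the
   lowest (row, column) pair, and negative branch-length estimates are
   clamped to zero. NJ is a consistent estimator for additive distances,
   and that is how the engine is validated — exact recovery of topology and
   branch lengths from additive matrices, agreement with an exhaustive
   ordinary-least-squares minimum-evolution search over all 15 five-taxon
   topologies, and agreement with `ape::nj` on noisy input. Balanced
   minimum-evolution search with topology rearrangement is out of scope;
   the neighbor-joining tree is the package's estimator, assessed on its
   own terms rather than against any other program's output bit for bit.

Newick export goes through `ape`; `cut_tree_groups()` offers a simple
longest-branch-removal partition of the leaves, a labelled approximation to
dendrogram clustering, not a reimplementation of any published method.

## Interactome zooming

Interaction graphs are confidence-weighted undirected gene graphs
(STRING-style combined scores on a 0–1 scale; a reader option rescales
0–1000 integers). Only edges with confidence **strictly** above the
threshold (default 0.7, the usual high-confidence cut) are kept; duplicate
pairs collapse to the maximum confidence and self-loops are dropped.

Given a query gene set, three nested views are extracted: level 1 keeps the
query genes plus every gene with at least one interaction with a query
gene; level 2 keeps genes interacting with at least two *distinct* query
genes; level 3 keeps the query genes only. The edge set is always the
subgraph induced by the selected nodes. Induction is a design choice — the
levels are defined purely by node selection, and a display built from a
node selection shows all edges among the selected nodes — and it is what
makes the nesting L3 ⊆ L2 ⊆ L1 hold universally. Connected components are
reported sorted by decreasing size, ties broken by the lexicographically
smallest member, so reports are stable. `seed_gene_zoom()` is sugar for the
per-gene view (seed gene plus its direct partners within a list, then
zoom); it is one reasonable interpretation of a per-gene neighborhood
display, flagged as such.

## GO fold enrichment and disease linkage

For two gene lists A and B, each GO term attached to at least one gene of
A ∪ B gets the percentage of A carrying it, the percentage of B, and their
ratio (fold): above 1 is over-representation in A, below 1
under-representation. This is a descriptive ratio — no p-values or
multiple-testing machinery are attached, because the ratio itself is the
reported statistic in this analysis style. Terms absent from B have
undefined fold, flagged `Inf` and excluded from rankings by default. Genes
are counted once per term (a gene with three terms contributes to three
records); no GO-graph ancestry propagation is performed — terms are taken
as listed. The default aspect filter is molecular function; a `min_pct`
display threshold mirrors the "only terms above X% of either set" reporting
convention. `nogo_fraction()` reports the genes carrying no term at all.

Morbidmap tables (`disorder | gene symbols | MIM | cytoband`, pipe or tab
separated, multi-gene rows indexed under every symbol) join against gene
lists by `disease_links()`; malformed rows are skipped with a warning
rather than aborting a long file.

## The synthetic generator

Real ISH annotation matrices at screen scale are not redistributable, so
every analysis here is exercised on synthetic data with controlled
structure:

* **Annotation matrices** use a latent-factor-plus-threshold construction,
  chosen over copulas for transparency and exact marginal control: each
  gene draws one standard-normal latent per tissue *block*; a tissue in a
  block of strength *s* observes `sqrt(s)·latent + sqrt(1-s)·noise`,
  thresholded at the normal quantiles of the tissue's cumulative target
  marginals. A configurable fraction of genes (default 0.165, the observed
  fraction of genes with no ISH signal anywhere in the 2000-gene screen) is
  forced negative in every tissue; thresholds for the remaining genes are
  adjusted so the *overall* marginals still hold in expectation, which is
  infeasible (and an error) when a tissue's negative-given-analyzed
  frequency is below that fraction. `na` cells are sprinkled independently
  at each tissue's `na` marginal (about 0.5% in the reference panel).
* **`preset_table1()`** sets the 25 per-tissue marginals to the published
  counts divided by 2000 and plants three tissue blocks at strength 0.6
  reflecting the three main branches of the published dendrogram
  (vestibular inner ear; mesoderm-derived/skeletal; nervous plus
  skin-derived). Block strength 0.6 on the latent scale is a deliberate
  middle setting: strong enough that the three blocks are recoverable as
  monophyletic groups from 2000 genes, weak enough that the recovery is a
  real statistical test rather than a tautology. The real screen's
  inter-tissue correlations are unpublished, so the block strengths are
  free parameters of the emulation, not estimates.
* **Interactomes** are planted-partition graphs with intra-module
  confidences drawn from a high range and inter-module from a lower one, so
  the 0.7 threshold mostly preserves modules. **GO tables** give an exact
  `round(nogo_fraction · n)` of genes no terms (default 0.183, the
  published no-GO fraction) and 1 + Poisson terms to the rest.
  **Morbidmaps** link `round(morbid_fraction · n)` genes (default 0.12) to
  synthetic disorders of 1–3 genes.

All generators are pure functions of (configuration, seed); a master seed
fans out to per-component `child_seed()`s so adding a generator never
perturbs the others.

### What passing tests do and do not show

The generator emulates marginal state frequencies, a never-expressed gene
subset, block-correlated tissues, sparse `na` cells, and modular
interactomes. It does **not** emulate gradated correlation within blocks,
tissue-specific expression archetypes, annotator disagreement, or the
long-tailed degree distributions of real interactomes. Tests passing on
synthetic data therefore demonstrate algorithmic correctness (against
independent oracles: truth-table evaluation for the sieve, exhaustive
neighbor counting for zooming, union-find for components, additive-matrix
recovery and exhaustive minimum-evolution search for trees) and recovery of
planted structure — not that any biological conclusion drawn from a real
screen is correct. Screen-scale headline figures that depend on the actual
annotation matrix and a specific interactome release (how many genes are
co-expressed in the five sensory epithelia, the exact sizes of the direct
interaction networks) are data, not algorithm properties, and are out of
reach without those inputs; the synthetic preset matches the published
marginal fractions by construction instead.

## Numerical and scale choices

* Percentages: one decimal, IEEE `%.1f` rounding (see above).
* Spearman: exact rank-then-Pearson; no large-sample approximation.
* NJ: branch lengths from the standard two-point formulas; clamping to zero
  only at emission, so internal distance updates are unaffected.
* Problem sizes in the test suite are chosen to make the oracles exhaustive
  yet fast: 200 random sieve and zoom cases of 15–25 genes, 100 random 4–8
  taxon trees, all 15 five-taxon topologies, and 20 replicates of the
  2000-gene, 25-tissue planted-block recovery. The whole suite runs in well
  under a minute.

## Known limitations

* The sieve grammar has no NOT and no ordered comparisons ("at least
  medium"); both are expressible via state sets and list complements.
* The dendrogram engine is plain NJ; for very non-additive distance
  matrices a balanced-ME search could find shorter trees.
* Fold enrichment is a ratio of percentages with no uncertainty measure;
  small counts make it unstable (a `min_pct` filter is the only guard).
* `disease_links` treats gene symbols as exact (case-insensitive) matches;
  no synonym or ortholog resolution is attempted.
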