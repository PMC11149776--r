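---
title: "Gene-family profiles: model, collapse semantics and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-family profiles: model, collapse semantics and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the data model, the semantics of the collapse
operations, the simulator and its scope, and the numerical and tie-breaking
choices made by `treeprofiles`. Every quantitative statement below is
asserted by the test suite or computed by `scripts/acceptance.R`; none is
an external empirical claim.

## The model

A **species tree** is a rooted tree with uniquely named leaves (extant
species) and named internal nodes (ancestral taxa); unnamed internals are
auto-named deterministically from their extreme leaf names. A **gene
family** is a rooted gene tree whose tips are extant genes (each assigned
to a species) or loss tips, and whose internal nodes carry an event —
`speciation` or `duplication` (`transfer` is accepted on input and treated
as a speciation-kind event) — and a **taxon**, the species-tree node the
gene-tree node maps to.

Two inference steps complete partially annotated input:

- **Taxon annotation.** Each node's taxon is the LCA (in the species tree)
  of the species of its extant descendants. Explicit taxa at or above that
  LCA are preserved; a node with no extant descendants must carry one.
- **Event inference (species overlap).** An unlabeled internal node is a
  duplication if and only if at least two of its children have overlapping
  species sets; otherwise it is a speciation. Pre-existing labels are never
  overwritten.

`validate_reconciliation()` checks the invariants (unique ids, child taxa
nested inside parent taxa, speciation children mapping to distinct species
children, well-formed tips, and — on normalized families — exact coverage
of every speciation's species children, with losses present where needed)
and returns a report rather than failing fast.

## Normalization

`normalize_family()` makes the reconciliation explicit in two idempotent
passes:

1. **Implied speciations.** On every edge that skips species-tree levels a
   chain of unary speciation nodes is inserted, one per skipped level. A
   duplication child whose span lies strictly below the duplication's taxon
   also receives a node at the duplication's taxon itself, so each
   subfamily's origin coincides with the duplication node. Inserted ids are
   `"<child_id>@<taxon>"` — anchored on the wrapped child, so several
   chains below one duplication cannot collide.
2. **Losses.** Every speciation node at taxon *t* gains one loss tip per
   child of *t* with no gene child mapping into it. This is one tip per
   **maximal lost clade**, labeled with the clade's taxon name — losses are
   reported at the highest taxonomic level at which the whole clade is
   absent, not once per extant species.

Normalization never changes any node's per-species gene counts, and
re-normalizing is the identity (both asserted on simulated families).

## Collapse semantics

A *view state* holds one or more normalized families over a shared species
tree plus the display state: per-family sets of collapsed gene nodes,
collapsed taxa, an optional depth limit and an optional root taxon.

- **Smart Collapse** collapses exactly the maximal duplication-free
  internal subtrees. Every collapsed subtree is congruent with the species
  tree, so its single profile row loses no information; every displayed
  internal node subtends a duplication (minimality), and re-application is
  a no-op. Bare tips are displayed as rows without being marked collapsed.
- **Collapse All** collapses each family to its root: one row per family.
- **Expand** removes one collapsed node and collapses the frontier of
  topmost strict descendants that are duplications or duplication-free
  internals — one duplication level at a time. Iterating expansion from
  Collapse All converges exactly to the Smart Collapse state (asserted);
  single-step equality holds only when duplications are not nested.
- **Collapse node** is idempotent, swallows collapsed descendants, and
  refuses nodes already strictly inside a collapsed subtree.
- **Collapse taxon** merges the taxon's columns into one and *cascades*:
  every displayed gene-tree node whose taxon lies inside a collapsed taxon
  is collapsed at its topmost such position. The invariant — no visible
  node maps into a collapsed taxon — is maintained by every operation and
  property-tested under random operation sequences.
- **Auto-collapse at depth d** collapses the species-tree internals at
  exactly depth *d* (root = 0), and the gene trees follow by the cascade.
- **Root taxon** restriction prunes every family to the chosen clade
  (dropping disjoint subtrees, splicing unary remnants) and drops the other
  columns.

Displayed sibling order is deterministic: children sort by the species-tree
position (leftmost leaf rank) of their taxon, then by decreasing extant
subtree size, then by id.

## Profiles and exact averaging

A profile row belongs to a displayed tip (gene, loss tip, or collapsed
subfamily); its **origin** is the tip's taxon and its **span** the extant
species below the origin. For a column *c* (an extant species or a
collapsed taxon) with member species *M*:

- if *M* ∩ span = ∅ the cell is an **outgroup blank** — the column
  predates the subfamily and carries no signal;
- otherwise the value is Σ counts over *M* ∩ span divided by |*M* ∩ span|,
  i.e. loss-zeros participate in the mean, outgroups do not;
- a value of 0 is a **loss-zero**, rendered as a gray 0 rather than blank.

Averages are held as exact rationals (integer numerator/denominator reduced
by gcd); equality checks in the tests are cross-multiplications, never
floating-point comparisons. Conservation — at every duplication, per
species, children-row counts sum to the parent-row count — is exact and
asserted across all fixtures.

## Rendering

SVG output is a pure function of (state, matrix): fixed geometry, all
coordinates formatted with `%.2f`, so output is byte-identical across runs
(asserted). Cell shading is `log2(1 + v) / log2(1 + vmax)` — log-scaled so
lineage-specific expansions stay distinguishable; branch width is
`1 + log2(n)` capped at 8 for *n* extant genes. The HTML page is fully
self-contained (no external assets): the SVG plus the serialized view state
(families, collapse sets, columns, row values) embedded as JSON. It is
static — it does not re-run collapse operations client-side; interactivity
beyond hover is out of scope for this package.

## The simulator

The generator exists to provide ground truth for property tests, not to fit
any biological data set. Its defaults are study conditions chosen a priori:

- **Species trees**: pure-birth (Yule) topologies grown by uniform leaf
  splitting, every edge of fixed length 1. Fixed lengths keep birth–death
  expectations in closed form; per-edge rate heterogeneity is out of scope.
- **Families**: one ancestral gene enters the root; along each edge every
  lineage duplicates at rate λ and dies at rate µ per unit length; at each
  speciation all survivors enter every child edge. The returned tree is
  pruned to survivors — extinct subtrees removed, one-survivor duplications
  and unary speciations spliced — and keeps true event/taxon labels.
- **Ground truth**: the retained duplication ids, the full event log, and
  the *observable* lost clades per subfamily component (maximal clades in
  the component's origin span reached by no surviving gene), keyed by the
  id the component top carries after normalization.

Calibration: the expected copy number per species is `exp((λ − µ)·T)` for
root-to-tip length *T*; the acceptance run checks the simulated mean at
2,000 replicates against this within 3 standard errors. Test problem sizes
(up to 50 species, hundreds of families) are the package's own choice of
desk-scale workload, selected to finish in minutes on one CPU.

## Known limitations

- Species-overlap inference is structurally unable to recover a
  duplication whose surviving children have disjoint species sets; with
  losses present the inferred duplication set is therefore a subset of the
  truth (exact recovery is asserted at µ = 0, subset behavior with losses).
- `merge_species_trees()` only resolves equal or nested leaf sets
  (superset wins; true conflicts error). It is not a supertree method.
- The live OMA / PANTHER adapters are best-effort against the public APIs;
  the cached-bundle path is the supported, fully tested offline route.
- Rational arithmetic uses R doubles for the (integer-valued) numerators
  and denominators; counts beyond 2^53 would lose exactness, far outside
  the intended scale.
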