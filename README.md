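# treeprofiles

Compact, information-preserving visualization of gene families: a reconciled
gene tree, its species tree, and a per-species copy-number matrix
(phylogenetic profile), linked through species-tree-guided collapse
operations.

## Background

Gene families evolve by speciation, duplication, and loss. A *reconciled*
gene tree maps every internal node of the family onto a node of the species
tree (its taxon) and labels it as a speciation or a duplication; losses
appear as explicit tips once the reconciliation is normalized against the
species tree. Families with many duplications are unwieldy to draw in full,
but most of their structure is redundant: any subtree without duplications
is congruent with the species tree, so given the species tree it can be
summarized by a single row of per-species gene counts without losing
information. Collapsing every *maximal duplication-free subtree* ("Smart
Collapse") therefore reduces a family to one profile row per subfamily while
remaining exactly invertible; the duplication skeleton — root plus
duplication nodes — is all the tree topology that remains to show.

The package implements this model end to end:

- **Core model** — species trees (Newick, via `ape`), gene trees with
  speciation/duplication/loss events, LCA taxon annotation,
  species-overlap event inference, and validation of the reconciliation
  invariants.
- **Normalization** — insertion of implied speciation nodes on edges that
  skip species-tree levels, and one loss tip per maximal lost clade; the
  result is idempotent and preserves all gene counts.
- **Collapse engine** — Smart Collapse, Collapse All,
  expand-to-next-duplication, collapse of species-tree taxa (columns merge
  and the collapse cascades to the gene trees), auto-collapse at a taxonomy
  depth, and restriction to a root taxon.
- **Profiles** — per-row, per-column copy numbers with three cell kinds:
  a count, a loss-zero (the taxon is in the row's span but the genes are
  gone), and an outgroup blank (the taxon predates the subfamily's origin).
  Averages that arise when a taxon with in-paralogs is collapsed are kept
  as exact rationals.
- **I/O** — a canonical JSON dialect (byte-stable, key-sorted), orthoXML
  import, cached fetching of public OMA / PANTHER families, and merging of
  per-family species trees.
- **Rendering** — deterministic SVG (species tree above the matrix, gene
  trees at the left, log-shaded heatmap cells) and a self-contained HTML
  page with the full view state embedded as JSON.
- **Simulator** — Yule species trees and birth–death gene family evolution
  with ground truth (true duplication set, event log, observable lost
  clades) for every property test in the suite.

## Worked example

Species tree `((A,B)AB,C)R` and a family with a duplication at the root:
subfamily X survives in all three species, subfamily Y only in A.

```r
library(treeprofiles)

species <- read_species_newick("((A,B)AB,C)R;")

doc <- '{
  "family_id": "F2",
  "root": {"id": "F2root", "children": [
    {"id": "X", "children": [
      {"id": "XAB", "children": [
        {"id": "a1", "species": "A"},
        {"id": "b1", "species": "B"}]},
      {"id": "c1", "species": "C"}]},
    {"id": "a2", "species": "A"}]}
}'
fam <- family_from_json(doc, species)
fam$root$event
#> [1] "duplication"
```

The root's children overlap in species A, so the root is inferred to be a
duplication. Normalizing adds the implied speciations and loss tips for
subfamily Y (lost in B and in C), after which the reconciliation validates:

```r
fam <- normalize_family(fam)
validate_reconciliation(fam)$ok
#> [1] TRUE
```

Smart Collapse reduces the family to its two duplication-free subfamilies,
and the profile matrix shows one row each — Y's zeros are loss-zeros, not
blanks, because Y originated at the root R:

```r
state <- smart_collapse(init_view(fam))
state$collapsed$F2
#> [1] "X"    "a2@R"
as.data.frame(profile_matrix(state))
#>   family  tip label taxon A B C
#> 1     F2    X     X     R 1 1 1
#> 2     F2 a2@R  a2@R     R 1 0 0
```

Collapsing the taxon AB merges its two columns; in-paralog counts are
averaged (Y has one gene in A and zero in B, hence 0.5):

```r
ab <- collapse_taxon(state, "AB")
as.data.frame(profile_matrix(ab))
#>   family  tip label taxon  AB C
#> 1     F2    X     X     R 1.0 1
#> 2     F2 a2@R  a2@R     R 0.5 0
```

`emit_svg(layout_view(state))` and `emit_html(state, "family.html")` write
the deterministic drawing and the self-contained page.

Simulated data comes with ground truth:

```r
st <- simulate_species_tree(8, seed = 42)
sim <- simulate_family(st, dup_rate = 0.3, loss_rate = 0.15, seed = 3)
sim
#> simulated_family: 4 retained duplication(s)
#> reconciled_family 'sim3': 14 genes in 8 species
state <- smart_collapse(init_view(normalize_family(sim$family)))
head(as.data.frame(profile_matrix(state)), 4)
#>   family    tip  label taxon s1 s5 s3 s8 s6 s2 s4 s7
#> 1   sim3 g@anc4 g@anc4  anc4  1  1 NA NA NA NA NA NA
#> 2   sim3 d3a_s3 d3a_s3    s3 NA NA  1 NA NA NA NA NA
#> 3   sim3 d3b_s3 d3b_s3    s3 NA NA  1 NA NA NA NA NA
#> 4   sim3 d1b_s8 d1b_s8    s8 NA NA NA  1 NA NA NA NA
```

## Command line

`exec/treeprofiles` wraps the same pipeline:

```sh
treeprofiles --json family.json --species species.nwk \
             --smart-collapse --out family.html --svg family.svg \
             --export-tsv profile.tsv
treeprofiles --fixture 12 --seed 7 --export-tsv sim.tsv
```

Exit codes: 0 success, 2 argument errors, 1 data/validation errors. Cached
`--oma`/`--panther` bundles under `--cache` make those sources fully
offline once populated.

## Limitations

- Species-overlap inference cannot recover a duplication whose surviving
  child lineages end up in disjoint species sets; with losses the inferred
  duplication set is a subset of the true one (exact when there are no
  losses).
- The HTML page is static: it embeds the current view state and matrix as
  JSON but does not re-run collapse operations client-side.
- The live OMA / PANTHER downloaders target the public APIs on a
  best-effort basis; the cache format is the supported offline path.

See `vignettes/gene-family-profiles.Rmd` for the model details, tie-breaking
rules and numerical choices.
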