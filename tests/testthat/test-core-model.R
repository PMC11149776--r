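test_that("taxon annotation assigns the LCA of extant descendants", {
  st <- toy_stree()
  f1 <- toy_f1(st)
  # node over {a1,b1} -> AB; leaves -> their species
  xab <- treeprofiles:::gn_find(f1$root, "XAB")
  expect_identical(xab$taxon, "AB")
  f2 <- toy_f2(st)
  expect_identical(treeprofiles:::gn_find(f2$root, "a2")$taxon, "A")
  # F2 root spans A,B,C,A -> LCA R (cross-checked against ape)
  expect_identical(f2$root$taxon, oracle_lca("((A,B)AB,C)R;", c("A", "B", "C")))
  expect_identical(f2$root$taxon, "R")
})

test_that("taxon annotation is idempotent and keeps explicit labels", {
  f2 <- toy_f2()
  again <- annotate_taxa(f2)
  expect_true(family_identical(f2, again))
  # explicit annotation above the LCA is preserved
  withtax <- gene_node("n", taxon = "R", children = list(
    gene_leaf("a", "A"), gene_leaf("b", "B")))
  fam <- reconciled_family("E", withtax, toy_stree())
  expect_identical(fam$root$taxon, "R")
})

test_that("annotation errors name the offending node", {
  st <- toy_stree()
  bad <- gene_node("r", children = list(gene_leaf("g1", "Z")))
  expect_error(reconciled_family("B", bad, st), "unknown species.*Z|g1")
  noext <- gene_node("r", children = list(gene_loss("l1", "C")))
  expect_error(reconciled_family("B2", noext, st), "no extant descendants")
})

test_that("species-overlap labeling separates speciations from duplications", {
  st <- toy_stree()
  # disjoint child species sets {A,B} vs {C} -> speciation
  f1 <- toy_f1(st)
  expect_identical(f1$root$event, "speciation")
  # overlapping sets {A} vs {A} -> duplication
  dup <- reconciled_family("D", gene_node("r", children = list(
    gene_leaf("x", "A"), gene_leaf("y", "A"))), st)
  expect_identical(dup$root$event, "duplication")
  # F2 root: {A,B,C} vs {A} overlap -> duplication
  expect_identical(toy_f2(st)$root$event, "duplication")
  # pre-existing labels are preserved
  forced <- reconciled_family("P", gene_node("r", event = "duplication",
    children = list(gene_leaf("x", "A"), gene_leaf("y", "B"))), st)
  expect_identical(forced$root$event, "duplication")
})

test_that("taxon of parent contains taxon of child on simulated families", {
  st0 <- NULL
  for (sim in sim_fixture_set(15)) {
    fam <- sim$family
    st <- fam$species_tree
    ok <- TRUE
    chk <- function(n) {
      for (ch in n$children) {
        if (!treeprofiles:::st_is_desc(st, treeprofiles:::st_resolve(st, ch$taxon),
                                       treeprofiles:::st_resolve(st, n$taxon)))
          ok <<- FALSE
        chk(ch)
      }
    }
    chk(annotate_taxa(fam)$root)
    expect_true(ok)
  }
})

test_that("event inference recovers the simulator's duplications", {
  # without losses every retained duplication has overlapping child spans:
  # recovery is exact
  for (i in 1:10) {
    st <- simulate_species_tree(10, seed = i)
    sim <- simulate_family(st, dup_rate = 0.4, loss_rate = 0, seed = 300 + i)
    if (sim$extinct) next
    stripped <- sim$family
    wipe <- function(n) {
      if (length(n$children) > 0) n$event <- NA_character_
      n$children <- lapply(n$children, wipe)
      n
    }
    stripped$root <- wipe(stripped$root)
    relabeled <- infer_events(annotate_taxa(stripped))
    got <- vapply(treeprofiles:::gn_collect(relabeled$root, function(n)
      identical(n$event, "duplication")), `[[`, "", "id")
    expect_setequal(got, sim$dup_node_ids)
  }
  # with losses, overlap inference can only miss duplications whose
  # surviving children became disjoint -- never invent one
  for (i in 1:10) {
    st <- simulate_species_tree(10, seed = i)
    sim <- simulate_family(st, dup_rate = 0.4, loss_rate = 0.3, seed = 600 + i)
    if (sim$extinct) next
    stripped <- sim$family
    wipe <- function(n) {
      if (length(n$children) > 0) n$event <- NA_character_
      n$children <- lapply(n$children, wipe)
      n
    }
    stripped$root <- wipe(stripped$root)
    relabeled <- infer_events(annotate_taxa(stripped))
    got <- vapply(treeprofiles:::gn_collect(relabeled$root, function(n)
      identical(n$event, "duplication")), `[[`, "", "id")
    expect_true(all(got %in% sim$dup_node_ids))
  }
})

test_that("validation accepts consistent families and reports violations", {
  st <- toy_stree()
  rep1 <- validate_reconciliation(toy_f1(st))
  expect_true(rep1$ok)
  expect_equal(nrow(rep1$violations), 0L)

  # child taxon above the parent's taxon
  bad <- toy_f1(st)
  fiddle <- function(n) {
    if (n$id == "XAB") n$children[[1]]$taxon <- "R"
    n$children <- lapply(n$children, fiddle)
    n
  }
  bad$root <- fiddle(bad$root)
  repb <- validate_reconciliation(bad)
  expect_false(repb$ok)
  expect_true("ancestor_taxon" %in% repb$violations$rule)

  # two speciation children mapping into the same species child
  twin <- gene_node("r", event = "speciation", taxon = "R", children = list(
    gene_leaf("x", "A"), gene_leaf("y", "A")))
  fam <- reconciled_family("T", twin, st, annotate = FALSE)
  fam <- annotate_taxa(fam)
  rept <- validate_reconciliation(fam)
  expect_false(rept$ok)
  expect_true("sibling_overlap" %in% rept$violations$rule)
  expect_match(rept$violations$message[rept$violations$rule == "sibling_overlap"],
               "sibling lineages map to same species child")
})

test_that("validation passes for every simulator output and normalization", {
  for (sim in sim_fixture_set(15)) {
    expect_true(validate_reconciliation(sim$family)$ok)
    expect_true(validate_reconciliation(normalize_family(sim$family))$ok)
  }
})
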