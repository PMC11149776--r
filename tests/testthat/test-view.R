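norm_f1 <- function(st = toy_stree()) normalize_family(toy_f1(st))
norm_f2 <- function(st = toy_stree()) normalize_family(toy_f2(st))

test_that("init_view starts fully expanded with shared columns", {
  st <- toy_stree()
  s <- init_view(norm_f2(st), st)
  expect_length(s$collapsed[["F2"]], 0L)
  expect_identical(visible_columns(s), c("A", "B", "C"))

  s2 <- init_view(list(norm_f1(st), norm_f2(st)), st)
  expect_identical(names(s2$families), c("F1", "F2"))
  expect_identical(visible_columns(s2), c("A", "B", "C"))

  other <- read_species_newick("((A,C)AC,B)R;")
  expect_error(init_view(list(norm_f1(st), normalize_family(toy_f1(other)))),
               "share one species tree")
  expect_error(init_view(norm_f2(st), st, root_taxon = "ZZ"), "unknown")
})

test_that("restricting to a root taxon prunes genes and losses outside it", {
  st <- toy_stree()
  s <- init_view(norm_f2(st), st, root_taxon = "AB")
  expect_identical(visible_columns(s), c("A", "B"))
  fam <- s$families[["F2"]]
  ids <- treeprofiles:::gn_ids(fam$root)
  expect_false("c1" %in% ids)
  expect_false(any(grepl("loss@C", ids)))
  # subfamily Y is reduced to its span-A subtree under AB
  expect_true("a2@AB" %in% ids)
  expect_true(validate_reconciliation(fam)$ok)
})

test_that("smart collapse keeps exactly the maximal duplication-free subtrees", {
  st <- toy_stree()
  s1 <- smart_collapse(init_view(norm_f1(st)))
  expect_identical(s1$collapsed[["F1"]], "X")          # whole family: 1 row
  expect_identical(tip_ids(s1, "F1"), "X")

  s2 <- smart_collapse(init_view(norm_f2(st)))
  expect_setequal(s2$collapsed[["F2"]], c("X", "a2@R"))  # X and Y rows
  expect_identical(smart_collapse(s2)$collapsed, s2$collapsed)  # idempotent
})

test_that("smart collapse is minimal and idempotent on simulated families", {
  for (sim in sim_fixture_set(12, dup_rate = 0.35)) {
    fam <- normalize_family(sim$family)
    s <- smart_collapse(init_view(fam))
    expect_identical(smart_collapse(s)$collapsed, s$collapsed)
    set <- s$collapsed[[fam$family_id]]
    chk <- function(n, under) {
      if (n$id %in% set) {
        expect_true(oracle_dup_free(n))
        under <- TRUE
      } else if (!under && length(n$children) > 0) {
        expect_false(oracle_dup_free(n))   # displayed internal subtends a dup
      }
      for (ch in n$children) chk(ch, under)
    }
    chk(fam$root, FALSE)
  }
})

test_that("collapse_all yields one row per family with family-wide counts", {
  st <- toy_stree()
  s <- collapse_all(init_view(list(norm_f1(st), norm_f2(st)), st))
  expect_identical(tip_ids(s, "F1"), "X")
  expect_identical(tip_ids(s, "F2"), "F2root")
  m <- as.data.frame(profile_matrix(s))
  expect_equal(nrow(m), 2L)
  expect_equal(unlist(m[m$family == "F2", c("A", "B", "C")], use.names = FALSE),
               c(2, 1, 1))
  expect_equal(unlist(m[m$family == "F1", c("A", "B", "C")], use.names = FALSE),
               c(1, 1, 1))
})

test_that("expanding reveals structure only down to the next duplications", {
  st <- toy_stree()
  # F2: expanding the collapsed root equals smart collapse
  s <- expand_node(collapse_all(init_view(norm_f2(st))), "F2", "F2root")
  expect_setequal(s$collapsed[["F2"]], c("X", "a2@R"))

  # nested duplication: the topmost duplication stays collapsed until
  # expanded itself
  fn <- normalize_family(toy_nested(st))
  sn <- expand_node(collapse_all(init_view(fn)), "FN", "FNroot")
  expect_true("dupAB" %in% sn$collapsed[["FN"]])
  expect_false(any(c("sp1", "sp2") %in% sn$collapsed[["FN"]]))
  expect_false(any(c("sp1", "sp2") %in% tip_ids(sn, "FN")))
  sn2 <- expand_node(sn, "FN", "dupAB")
  expect_setequal(intersect(c("sp1", "sp2"), sn2$collapsed[["FN"]]),
                  c("sp1", "sp2"))

  # expanding a non-collapsed node warns and does nothing
  expect_warning(s_same <- expand_node(s, "F2", "c1"), "not collapsed")
  expect_identical(s_same$collapsed, s$collapsed)
})

test_that("collapse_node follows the set algebra", {
  st <- toy_stree()
  s <- smart_collapse(init_view(norm_f2(st)))
  s2 <- collapse_node(s, "F2", "F2root")
  expect_identical(s2$collapsed, collapse_all(init_view(norm_f2(st)))$collapsed)
  # collapsing an extant leaf gives a single-gene row
  s3 <- collapse_node(init_view(norm_f1(st)), "F1", "a1")
  expect_true("a1" %in% s3$collapsed[["F1"]])
  expect_true("a1" %in% tip_ids(s3, "F1"))
  # idempotent; error under an already collapsed subtree
  expect_identical(collapse_node(s2, "F2", "F2root")$collapsed, s2$collapsed)
  expect_error(collapse_node(s2, "F2", "a1"), "inside a collapsed subtree")
})

test_that("iterated expansion from a collapsed root reaches smart collapse", {
  # expand_node reveals one duplication level at a time; expanding every
  # collapsed duplication until none is left converges exactly to the
  # Smart Collapse state
  for (sim in sim_fixture_set(6, dup_rate = 0.35)) {
    fam <- normalize_family(sim$family)
    fid <- fam$family_id
    if (treeprofiles:::gn_is_tip(fam$root)) next
    s <- collapse_all(init_view(fam))
    repeat {
      todo <- Filter(function(id) {
        !oracle_dup_free(treeprofiles:::gn_find(fam$root, id))
      }, s$collapsed[[fid]])
      if (length(todo) == 0) break
      s <- expand_node(s, fid, todo[[1]])
    }
    want <- smart_collapse(init_view(fam))
    expect_setequal(s$collapsed[[fid]], want$collapsed[[fid]])
    expect_identical(tip_ids(s, fid), tip_ids(want, fid))
  }
})

test_that("collapsing a taxon merges columns and cascades to gene nodes", {
  st <- toy_stree()
  s <- smart_collapse(init_view(norm_f2(st)))
  s2 <- collapse_taxon(s, "AB")
  expect_identical(visible_columns(s2), c("AB", "C"))
  m <- as.data.frame(profile_matrix(s2))
  expect_equal(m$AB[m$tip == "X"], 1)        # (1+1)/2
  expect_equal(m$AB[m$tip == "a2@R"], 0.5)   # (1+0)/2
  # collapsing the root cascades every family to its root row
  s3 <- collapse_taxon(s, "R")
  expect_identical(visible_columns(s3), "R")
  expect_identical(tip_ids(s3, "F2"), "F2root")
  # idempotent; extant species rejected
  expect_identical(collapse_taxon(s2, "AB")$collapsed_taxa, s2$collapsed_taxa)
  expect_error(collapse_taxon(s, "A"), "extant species")
})

test_that("auto-collapse at depth collapses exactly the depth-d internals", {
  st <- toy_stree()
  s <- init_view(norm_f2(st))
  expect_identical(visible_columns(auto_collapse_depth(s, 1)), c("AB", "C"))
  expect_identical(visible_columns(auto_collapse_depth(s, 0)), "R")
  expect_identical(visible_columns(auto_collapse_depth(s, 5)), c("A", "B", "C"))
})

test_that("visible tips are ordered by species position then subtree size", {
  st <- toy_stree()
  s <- smart_collapse(init_view(norm_f2(st)))
  # X (4 extant genes... larger span) before Y at the root duplication
  expect_identical(tip_ids(s, "F2"), c("X", "a2@R"))
  # fully expanded F1: leaves in species order
  s1 <- init_view(norm_f1(st))
  expect_identical(tip_ids(s1, "F1"), c("a1", "b1", "c1"))
})

test_that("the cascade invariant survives random operation sequences", {
  for (sim in sim_fixture_set(5, dup_rate = 0.35)) {
    fam <- normalize_family(sim$family)
    st <- fam$species_tree
    fid <- fam$family_id
    s <- smart_collapse(init_view(fam))
    set.seed(sum(utf8ToInt(fid)))
    internals <- setdiff(st$name, st$name[st$leaves])
    for (k in 1:12) {
      op <- sample(c("ctaxon", "cnode", "expand", "smart", "all"), 1)
      s <- tryCatch(switch(op,
        ctaxon = collapse_taxon(s, sample(internals, 1)),
        cnode = collapse_node(s, fid, sample(tip_ids(s, fid), 1)),
        expand = {
          cand <- s$collapsed[[fid]]
          if (length(cand)) expand_node(s, fid, sample(cand, 1)) else s
        },
        smart = smart_collapse(s),
        all = collapse_all(s)),
        error = function(e) s, warning = function(w) s)
      # invariant: every gene node inside a collapsed taxon is at/below a
      # collapsed gene node, and no collapsed node nests inside another
      set <- s$collapsed[[fid]]
      chk <- function(n, under) {
        if (n$id %in% set) {
          expect_false(under)
          under <- TRUE
        }
        if (!under) {
          expect_false(treeprofiles:::in_collapsed_taxon(s, n$taxon))
        }
        for (ch in n$children) chk(ch, under)
      }
      chk(fam$root, FALSE)
    }
  }
})
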