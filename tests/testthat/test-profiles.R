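test_that("profile rows carry counts, loss-zeros and outgroup-empties", {
  st <- toy_stree()
  s <- smart_collapse(init_view(normalize_family(toy_f2(st))))
  m <- profile_matrix(s)
  rows <- setNames(m$rows, vapply(m$rows, `[[`, "", "tip_id"))
  # subfamily Y (origin R): present in A, lost in B and C -- never outgroup
  expect_identical(rows[["a2@R"]]$kind, c("COUNT", "LOST", "LOST"))
  expect_equal(rows[["a2@R"]]$value, c(1, 0, 0))
  expect_identical(rows[["X"]]$kind, rep("COUNT", 3))

  # a tip whose origin is AB leaves column C empty (outgroup)
  s1 <- init_view(normalize_family(toy_f1(st)))
  s1 <- collapse_node(s1, "F1", "XAB")
  r <- profile_row(visible_tips(s1, "F1")[[1]], s1)
  expect_identical(r$origin_taxon, "AB")
  expect_identical(r$kind, c("COUNT", "COUNT", "OUTGROUP"))
  expect_true(is.na(r$value[3]))
})

test_that("outgroup cells appear exactly where span and column are disjoint", {
  for (sim in sim_fixture_set(8, dup_rate = 0.35)) {
    fam <- normalize_family(sim$family)
    st <- fam$species_tree
    s <- smart_collapse(init_view(fam))
    cols <- visible_columns(s)
    for (tip in visible_tips(s, fam$family_id)) {
      r <- profile_row(tip, s, cols)
      span <- treeprofiles:::st_species_names_under(
        st, treeprofiles:::st_resolve(st, tip$taxon))
      expect_identical(r$kind == "OUTGROUP", !(cols %in% span))
    }
  }
})

test_that("uncollapsed profile cells equal the leaf-count oracle", {
  for (sim in sim_fixture_set(10, dup_rate = 0.3)) {
    fam <- normalize_family(sim$family)
    s <- smart_collapse(init_view(fam))
    cols <- visible_columns(s)
    for (tip in visible_tips(s, fam$family_id)) {
      r <- profile_row(tip, s, cols)
      cnt <- oracle_counts(tip)
      for (j in seq_along(cols)) {
        if (r$kind[j] == "OUTGROUP") next
        want <- if (cols[j] %in% names(cnt)) as.numeric(cnt[[cols[j]]]) else 0
        got <- if (r$kind[j] == "LOST") 0 else r$value[j]
        expect_equal(got, want)
      }
    }
  }
})

test_that("taxon-collapsed columns average in-paralogs exactly", {
  # exact rational equality: num/den cross-multiplication, no floats
  for (sim in sim_fixture_set(8, dup_rate = 0.3)) {
    fam <- normalize_family(sim$family)
    st <- fam$species_tree
    s <- smart_collapse(init_view(fam))
    set.seed(nchar(fam$family_id) + length(st$id))
    tx <- sample(setdiff(st$name, st$name[st$leaves]), 1)
    s2 <- collapse_taxon(s, tx)
    m2 <- profile_matrix(s2)
    j <- match(tx, m2$columns)
    if (is.na(j)) next
    ext <- treeprofiles:::st_species_names_under(
      st, treeprofiles:::st_resolve(st, tx))
    for (r in m2$rows) {
      if (r$kind[j] == "OUTGROUP") next
      span <- treeprofiles:::st_species_names_under(
        st, treeprofiles:::st_resolve(st, r$origin_taxon))
      I <- intersect(ext, span)
      tip <- treeprofiles:::gn_find(s2$families[[r$family_id]]$root, r$tip_id)
      cnt <- oracle_counts(tip)
      tot <- sum(vapply(I, function(sp)
        if (sp %in% names(cnt)) as.integer(cnt[[sp]]) else 0L, 0L))
      expect_identical(r$num[j] * length(I), tot * r$den[j])
    }
  }
})

test_that("conservation holds row-wise under expansion", {
  # per species: children rows at a duplication sum to the parent row
  st <- toy_stree()
  fam <- normalize_family(toy_f2(st))
  s_parent <- collapse_all(init_view(fam))
  s_kids <- smart_collapse(init_view(fam))
  mp <- as.data.frame(profile_matrix(s_parent))
  mk <- as.data.frame(profile_matrix(s_kids))
  for (sp in c("A", "B", "C")) {
    expect_equal(sum(mk[[sp]], na.rm = TRUE), mp[[sp]][1])
  }
})

test_that("matrices stack families over shared columns", {
  st <- toy_stree()
  fams <- list(normalize_family(toy_f1(st)), normalize_family(toy_f2(st)))
  m <- profile_matrix(collapse_all(init_view(fams, st)))
  expect_length(m$rows, 2L)
  expect_identical(m$columns, c("A", "B", "C"))
  expect_equal(m$vmax, 2)
  fams_m <- vapply(m$rows, `[[`, "", "family_id")
  expect_identical(fams_m, c("F1", "F2"))
})

test_that("TSV export renders LOST as 0 and OUTGROUP as empty", {
  st <- toy_stree()
  s <- smart_collapse(init_view(normalize_family(toy_f2(st))))
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- profile_matrix(s)
  write_profile_tsv(m, path)
  lines <- readLines(path)
  expect_identical(lines[1], paste(c("family", "tip", "label", "taxon",
                                     "A", "B", "C"), collapse = "\t"))
  y <- strsplit(grep("a2@R", lines, value = TRUE), "\t")[[1]]
  expect_identical(y[5:7], c("1", "0", "0"))

  # fractional averages and outgroups
  s2 <- collapse_taxon(smart_collapse(init_view(normalize_family(toy_f2(st)))), "AB")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(profile_matrix(s2), p2)
  y2 <- strsplit(grep("a2@R", readLines(p2), value = TRUE), "\t")[[1]]
  expect_identical(y2[5], "0.5")

  s3 <- collapse_node(init_view(normalize_family(toy_f1(st))), "F1", "XAB")
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(profile_matrix(s3), p3)
  r3 <- strsplit(grep("XAB", readLines(p3), value = TRUE), "\t")[[1]]
  expect_identical(r3[5:6], c("1", "1"))
  expect_true(length(r3) == 6 || r3[7] == "")   # trailing outgroup is empty
})
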