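# Shared toy fixtures: species tree S = ((A,B)AB,C)R with two families.
#   F1: a single-copy family congruent with S (no duplication).
#   F2: a root duplication at R; subfamily X spans all species, subfamily Y
#       is the single extant leaf a2 in A.
# Plus a nested-duplication variant and a tiny orthoXML document.

toy_stree <- function() read_species_newick("((A,B)AB,C)R;")

toy_f1 <- function(st = toy_stree()) {
  reconciled_family("F1", gene_node("X", children = list(
    gene_node("XAB", children = list(gene_leaf("a1", "A"),
                                     gene_leaf("b1", "B"))),
    gene_leaf("c1", "C"))), st)
}

toy_f2 <- function(st = toy_stree()) {
  X <- gene_node("X", children = list(
    gene_node("XAB", children = list(gene_leaf("a1", "A"),
                                     gene_leaf("b1", "B"))),
    gene_leaf("c1", "C")))
  reconciled_family("F2", gene_node("F2root", children = list(
    X, gene_leaf("a2", "A"))), st)
}

# root duplication at R; one subfamily holds a nested duplication at AB
toy_nested <- function(st = toy_stree()) {
  dupAB <- gene_node("dupAB", event = "duplication", children = list(
    gene_node("sp1", children = list(gene_leaf("a1", "A"),
                                     gene_leaf("b1", "B"))),
    gene_node("sp2", children = list(gene_leaf("a3", "A"),
                                     gene_leaf("b3", "B")))))
  reconciled_family("FN", gene_node("FNroot", event = "duplication",
                                    children = list(dupAB,
                                                    gene_leaf("a2", "A"))),
                    st)
}

toy_orthoxml <- function() {
  paste0(
    '<orthoXML xmlns="http://orthoXML.org/2011/" version="0.3" origin="t" originVersion="1">',
    '<species name="A" NCBITaxId="1"><database name="db" version="1"><genes>',
    '<gene id="1" protId="gA1"/><gene id="2" protId="gA2"/></genes></database></species>',
    '<species name="B" NCBITaxId="2"><database name="db" version="1"><genes>',
    '<gene id="3" protId="gB1"/></genes></database></species>',
    '<species name="C" NCBITaxId="3"><database name="db" version="1"><genes>',
    '<gene id="4" protId="gC1"/></genes></database></species>',
    '<groups><orthologGroup id="fam1">',
    '<orthologGroup><paralogGroup><geneRef id="1"/><geneRef id="2"/></paralogGroup>',
    '<geneRef id="3"/></orthologGroup>',
    '<geneRef id="4"/></orthologGroup></groups></orthoXML>')
}

# --- independent mini-oracles (deliberately not the package's code paths) ---

# LCA by name via ape on the same newick
oracle_lca <- function(newick, species) {
  phy <- ape::read.tree(text = newick)
  if (length(species) == 1L) return(species)
  lab <- c(phy$tip.label, phy$node.label)
  lab[ape::getMRCA(phy, species)]
}

# per-species leaf counts by direct recursion over the node list
oracle_counts <- function(node) {
  acc <- c()
  rec <- function(n) {
    if (identical(n$event, "leaf")) acc <<- c(acc, n$species)
    for (ch in n$children) rec(ch)
  }
  rec(node)
  if (is.null(acc)) integer(0) else table(acc)
}

# add named integer count vectors
sum_counts <- function(lst) {
  sp <- sort(unique(unlist(lapply(lst, names))))
  vapply(sp, function(s)
    sum(vapply(lst, function(a) if (s %in% names(a)) a[[s]] else 0L, 0L)),
    0L)
}

# no duplication anywhere below (independent of the collapse engine)
oracle_dup_free <- function(n) {
  !identical(n$event, "duplication") &&
    all(vapply(n$children, oracle_dup_free, TRUE))
}

sim_fixture_set <- function(n = 40, dup_rate = 0.3, loss_rate = 0.15,
                            seed_base = 7000L) {
  out <- list()
  for (i in seq_len(n)) {
    st <- simulate_species_tree(4L + (i %% 25L), seed = i)
    sim <- simulate_family(st, dup_rate, loss_rate, seed = seed_base + i)
    if (!sim$extinct) out[[length(out) + 1L]] <- sim
  }
  out
}

tip_ids <- function(state, fid) vapply(visible_tips(state, fid), `[[`, "", "id")
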