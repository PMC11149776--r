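# Synthetic-data generator: pure-birth species trees and birth-death gene
# families evolved along them, with ground truth (true event labels, the
# retained duplication set and the observable lost clades) for every
# property check in the suite.
#
# All randomness is seeded locally: identical arguments give identical
# output and the caller's RNG state is left untouched.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a species tree
#'
#' Pure-birth (Yule) topology: starting from a two-species cherry, a leaf
#' chosen uniformly at random is split until `n_species` tips exist.  Every
#' edge gets the same fixed length, which keeps birth-death expectations in
#' closed form (rates are per unit length).
#'
#' @param n_species number of extant species (>= 2).
#' @param seed integer seed; identical seeds give identical trees.
#' @param branch_length fixed per-edge length (default 1).
#' @return A `species_tree` with leaves `s1..sN` and internals `anc1..`.
#' @export
simulate_species_tree <- function(n_species, seed, branch_length = 1) {
  stopifnot(n_species >= 2)
  with_seed(seed, {
    id <- c("anc1", "s1", "s2")
    parent <- c(NA, "anc1", "anc1")
    children <- list(c("s1", "s2"), character(0), character(0))
    n_leaves <- 2L
    n_anc <- 1L
    while (n_leaves < n_species) {
      leaves <- which(lengths(children) == 0L)
      pick <- leaves[sample.int(length(leaves), 1L)]
      n_anc <- n_anc + 1L
      new_anc <- paste0("anc", n_anc)
      a <- paste0("s", n_leaves + 1L)
      # the picked leaf keeps its name below the new internal node
      old <- id[pick]
      id[pick] <- new_anc
      if (!is.na(parent[pick])) {
        p <- which(id == parent[pick])
        children[[p]][children[[p]] == old] <- new_anc
      }
      id <- c(id, old, a)
      parent <- c(parent, new_anc, new_anc)
      children[[pick]] <- c(old, a)
      children <- c(children, list(character(0), character(0)))
      n_leaves <- n_leaves + 1L
    }
    species_tree(id, parent, children,
                 edge_length = c(NA_real_,
                                 rep(branch_length, length(id) - 1L)))
  })
}

#' Simulate a gene family along a species tree
#'
#' One ancestral gene enters the root; along every species-tree edge each
#' lineage duplicates at rate `dup_rate` and dies at rate `loss_rate` per
#' unit branch length (continuous time); at every speciation all surviving
#' lineages enter every child edge.  The returned family is pruned to
#' survivors: extinct subtrees are removed, unobservable duplications (one
#' surviving child) and unary speciation chains are spliced out, and all
#' retained nodes keep their true event and taxon labels.
#'
#' @param stree a `species_tree` (edge lengths must be set; the simulated
#'   trees have them).
#' @param dup_rate,loss_rate nonnegative event rates per unit length.
#' @param seed integer seed.
#' @param family_id id for the resulting family.
#' @return A `simulated_family`: list with `family` (`reconciled_family`,
#'   or NULL when the whole family went extinct), `extinct` flag,
#'   `event_log` (data.frame: event, taxon, lineage, time),
#'   `dup_node_ids` (true retained duplications) and `observable_losses`
#'   (per subfamily component, see [observable_losses()]).
#' @export
simulate_family <- function(stree, dup_rate, loss_rate, seed,
                            family_id = paste0("sim", seed)) {
  stopifnot(dup_rate >= 0, loss_rate >= 0)
  st <- stree
  log_ev <- list()
  note <- function(event, taxon, lineage, time)
    log_ev[[length(log_ev) + 1L]] <<- data.frame(
      event = event, taxon = taxon, lineage = lineage, time = time,
      stringsAsFactors = FALSE)
  dup_k <- 0L
  rate <- dup_rate + loss_rate

  root <- with_seed(seed, {
    sim_edge <- function(lin, v, remaining) {
      # lineage `lin` travelling towards species node v
      tx <- st$name[v]
      repeat {
        w <- if (rate > 0) stats::rexp(1L, rate) else Inf
        if (w >= remaining) break
        remaining <- remaining - w
        if (stats::runif(1L) < dup_rate / rate) {
          dup_k <<- dup_k + 1L
          did <- paste0("d", dup_k)
          note("duplication", tx, lin, remaining)
          a <- sim_edge(paste0(did, "a"), v, remaining)
          b <- sim_edge(paste0(did, "b"), v, remaining)
          if (is.null(a) && is.null(b)) return(NULL)
          if (is.null(a)) return(b)          # unobservable duplication
          if (is.null(b)) return(a)
          return(gene_node(did, event = "duplication", taxon = tx,
                           children = list(a, b)))
        }
        note("loss", tx, lin, remaining)
        return(NULL)
      }
      # reached species node v
      kids_v <- st$children[[v]]
      if (length(kids_v) == 0L) {
        return(gene_leaf(paste0(lin, "_", tx), species = tx))
      }
      sub <- lapply(kids_v, function(c_)
        sim_edge(lin, c_, st$edge_length[c_]))
      sub <- Filter(Negate(is.null), sub)
      if (length(sub) == 0L) return(NULL)
      if (length(sub) == 1L) return(sub[[1L]])   # unary speciation: splice
      gene_node(paste0(lin, "@", tx), event = "speciation", taxon = tx,
                children = sub)
    }
    v0 <- st$root
    kids0 <- st$children[[v0]]
    if (length(kids0) == 0L) stop("species tree has a single node")
    sub <- Filter(Negate(is.null), lapply(kids0, function(c_)
      sim_edge("g", c_, st$edge_length[c_])))
    if (length(sub) == 0L) NULL
    else if (length(sub) == 1L) sub[[1L]]
    else gene_node(paste0("g@", st$name[v0]), event = "speciation",
                   taxon = st$name[v0], children = sub)
  })

  event_log <- if (length(log_ev)) do.call(rbind, log_ev)
    else data.frame(event = character(0), taxon = character(0),
                    lineage = character(0), time = numeric(0),
                    stringsAsFactors = FALSE)
  if (is.null(root)) {
    return(structure(list(family = NULL, extinct = TRUE,
                          event_log = event_log,
                          dup_node_ids = character(0),
                          observable_losses = list()),
                     class = "simulated_family"))
  }
  fam <- structure(list(family_id = family_id, root = root,
                        species_tree = st, normalized = FALSE),
                   class = "reconciled_family")
  dup_ids <- vapply(gn_collect(fam$root,
                               function(n) identical(n$event, "duplication")),
                    `[[`, "", "id")
  structure(list(family = fam, extinct = FALSE, event_log = event_log,
                 dup_node_ids = dup_ids,
                 observable_losses = observable_losses(fam)),
            class = "simulated_family")
}

#' @export
print.simulated_family <- function(x, ...) {
  if (x$extinct) cat("simulated_family: extinct (no survivors)\n")
  else {
    cat("simulated_family:", length(x$dup_node_ids),
        "retained duplication(s)\n")
    print(x$family)
  }
  invisible(x)
}

#' Write a simulated family as offline fixtures
#'
#' Emits the family in the native JSON dialect next to the species tree in
#' newick, so a simulated data set can be re-read through the standard
#' readers.
#'
#' @param sim a `simulated_family`.
#' @param dir output directory (created if needed).
#' @return Paths of the two files, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(!sim$extinct)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fj <- file.path(dir, paste0(sim$family$family_id, ".json"))
  fn <- file.path(dir, "species.nwk")
  write_family_json(sim$family, fj)
  writeLines(species_newick(sim$family$species_tree), fn)
  invisible(c(fj, fn))
}
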