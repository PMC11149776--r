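# Species tree: rooted, possibly multifurcating taxonomy.
#
# Stored flat: nodes indexed 1..n in preorder, child order preserved from
# input.  The left-to-right tip sequence defines profile column order and is
# immutable after construction.

#' Build a species tree from parent/child relations
#'
#' Low-level constructor used by [read_species_newick()] and the simulator.
#' Nodes are supplied in any order; they are re-indexed in preorder so that
#' the left-to-right leaf sequence is stable.
#'
#' @param id character vector of unique node ids.
#' @param parent character vector of parent ids (`NA` for the root).
#' @param children list of character vectors giving each node's ordered
#'   children (ids).
#' @param name display names; defaults to `id`.
#' @param edge_length numeric branch length to the parent (`NA` allowed);
#'   retained but unused by the view algebra.
#' @return An object of class `species_tree`.
#' @export
species_tree <- function(id, parent, children, name = id, edge_length = NULL) {
  stopifnot(length(id) == length(parent), length(id) == length(children))
  name <- as.character(name)  # force now: `id` is permuted below
  if (anyDuplicated(id)) {
    stop("species tree node ids must be unique: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (is.null(edge_length)) edge_length <- rep(NA_real_, length(id))
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("species tree must have exactly one root")

  pos <- stats::setNames(seq_along(id), id)
  # preorder re-index, preserving child order
  order_ids <- character(0)
  walk <- function(i) {
    order_ids[[length(order_ids) + 1L]] <<- id[[i]]
    for (ch in children[[i]]) walk(pos[[ch]])
  }
  walk(root)
  perm <- pos[order_ids]
  id <- id[perm]; parent <- parent[perm]; name <- name[perm]
  children <- children[perm]; edge_length <- edge_length[perm]
  pos <- stats::setNames(seq_along(id), id)

  par_idx <- ifelse(is.na(parent), NA_integer_, pos[parent])
  kids <- lapply(children, function(ch) unname(pos[ch]))
  n <- length(id)

  depth <- integer(n)
  for (i in seq_len(n)[-1L]) depth[i] <- depth[par_idx[i]] + 1L

  is_leaf <- lengths(kids) == 0L
  leaves <- which(is_leaf)           # preorder = left-to-right tip order
  leaf_rank <- rep(NA_integer_, n)
  leaf_rank[leaves] <- seq_along(leaves)

  # per node: leftmost leaf rank and number of extant leaves in the subtree
  leftmost <- integer(n); nleaf <- integer(n)
  for (i in rev(seq_len(n))) {
    if (is_leaf[i]) {
      leftmost[i] <- leaf_rank[i]; nleaf[i] <- 1L
    } else {
      leftmost[i] <- min(leftmost[kids[[i]]]); nleaf[i] <- sum(nleaf[kids[[i]]])
    }
  }

  structure(
    list(id = id, name = name, parent = par_idx, children = kids,
         depth = depth, edge_length = edge_length, root = 1L,
         leaves = leaves, leaf_rank = leaf_rank, leftmost = leftmost,
         nleaf = nleaf, index = pos),
    class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("species_tree: %d nodes, %d extant species, height %d\n",
              length(x$id), length(x$leaves), max(x$depth)))
  cat("tips:", paste(x$name[x$leaves], collapse = ", "), "\n")
  invisible(x)
}

st_n_nodes <- function(st) length(st$id)
st_is_leaf <- function(st, v) lengths(st$children[v]) == 0L

st_resolve <- function(st, name_or_idx) {
  if (is.numeric(name_or_idx)) return(as.integer(name_or_idx))
  i <- st$index[name_or_idx]
  if (anyNA(i)) {
    stop("unknown taxon/species name: ",
         paste(name_or_idx[is.na(i)], collapse = ", "), call. = FALSE)
  }
  unname(i)
}

st_ancestors <- function(st, v) {
  # v and all its ancestors up to the root, bottom-up
  out <- integer(0)
  while (!is.na(v)) { out <- c(out, v); v <- st$parent[v] }
  out
}

#' @keywords internal
st_is_desc <- function(st, a, b) {
  # is a a descendant of b (or b itself)?
  while (!is.na(a)) {
    if (a == b) return(TRUE)
    a <- st$parent[a]
  }
  FALSE
}

st_lca <- function(st, v) {
  v <- unique(v)
  if (length(v) == 0L) stop("LCA of an empty node set is undefined")
  anc <- st_ancestors(st, v[1L])
  for (x in v[-1L]) anc <- intersect(anc, st_ancestors(st, x))
  anc[[1L]]  # anc is ordered bottom-up, so the first entry is the deepest
}

st_path <- function(st, top, bottom) {
  # nodes from top to bottom inclusive; error if not on one lineage
  path <- rev(st_ancestors(st, bottom))
  i <- match(top, path)
  if (is.na(i)) stop("taxa not on one lineage: ", st$id[top], " .. ", st$id[bottom])
  path[i:length(path)]
}

st_leaves_under <- function(st, v) {
  # extant leaf indices in subtree(v), left-to-right
  if (st_is_leaf(st, v)) return(v)
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[[1L]]; stack <- stack[-1L]
    k <- st$children[[x]]
    if (length(k) == 0L) out <- c(out, x) else stack <- c(k, stack)
  }
  out
}

st_species_names_under <- function(st, v) st$name[st_leaves_under(st, v)]

#' Read a species tree from a newick string or file
#'
#' Child order is preserved as written; branch lengths are parsed and kept
#' (the view algebra ignores them).  Unnamed internal nodes are auto-named
#' from the alphabetically extreme leaf names below them so that ids are
#' stable across runs.
#'
#' @param text a newick string, or the path of a file holding one.
#' @return A `species_tree`.
#' @examples
#' st <- read_species_newick("((A,B)AB,C)R;")
#' st$name[st$leaves]
#' @export
read_species_newick <- function(text) {
  if (length(text) == 1L && !grepl("\\(", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("newick parse error: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("newick parse error: empty or malformed input")
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf names in species tree: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  n <- ntip + nnode
  lab <- c(phy$tip.label, if (!is.null(phy$node.label)) phy$node.label
           else rep("", nnode))
  lab[is.na(lab)] <- ""

  kids <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; c_ <- phy$edge[i, 2L]
    kids[[p]] <- c(kids[[p]], c_)
  }
  par <- rep(NA_integer_, n)
  elen <- rep(NA_real_, n)
  for (i in seq_len(nrow(phy$edge))) {
    par[phy$edge[i, 2L]] <- phy$edge[i, 1L]
    if (!is.null(phy$edge.length)) elen[phy$edge[i, 2L]] <- phy$edge.length[i]
  }

  # auto-name unnamed internals from extreme leaf names; suffix on collision
  tips_under <- function(v) {
    if (v <= ntip) return(lab[v])
    unlist(lapply(kids[[v]], tips_under))
  }
  for (v in seq.int(ntip + 1L, n)) {
    if (!nzchar(lab[v])) {
      tl <- sort(tips_under(v))
      lab[v] <- paste0(tl[1L], "-", tl[length(tl)])
    }
  }
  while (anyDuplicated(lab)) {
    d <- which(duplicated(lab))
    lab[d] <- paste0(lab[d], "_", seq_along(d))
  }

  species_tree(id = lab, parent = ifelse(is.na(par), NA, lab[par]),
               children = lapply(kids, function(k) lab[k]),
               edge_length = elen)
}

#' Serialize a species tree to newick
#'
#' @param st a `species_tree`.
#' @param with_lengths include branch lengths when present.
#' @return A newick string (with trailing semicolon).
#' @export
species_newick <- function(st, with_lengths = TRUE) {
  rec <- function(v) {
    kids <- st$children[[v]]
    core <- if (length(kids) == 0L) st$name[v]
            else paste0("(", paste(vapply(kids, rec, ""), collapse = ","),
                        ")", st$name[v])
    if (with_lengths && !is.na(st$edge_length[v]))
      core <- paste0(core, ":", format(st$edge_length[v], digits = 12))
    core
  }
  paste0(rec(st$root), ";")
}

#' Merge species trees fetched for several families
#'
#' Trees must agree: for every pair, the larger tree restricted to the
#' smaller one's species must present the same nested clades.  The tree with
#' the largest species set is returned.
#'
#' @param trees list of `species_tree` objects.
#' @return A single `species_tree`.
#' @export
merge_species_trees <- function(trees) {
  stopifnot(length(trees) >= 1L)
  if (length(trees) == 1L) return(trees[[1L]])
  clade_sets <- function(st, keep) {
    # nested leaf-name sets restricted to `keep`, dropping trivial ones
    out <- list()
    for (v in seq_along(st$id)) {
      s <- intersect(st_species_names_under(st, v), keep)
      if (length(s) > 1L) out[[length(out) + 1L]] <- sort(s)
    }
    unique(out)
  }
  best <- trees[[1L]]
  for (tr in trees[-1L]) {
    a <- st_species_names_under(best, best$root)
    b <- st_species_names_under(tr, tr$root)
    shared <- intersect(a, b)
    if (length(shared) < length(a) && length(shared) < length(b)) {
      stop("species trees overlap only partially; cannot merge")
    }
    ca <- clade_sets(best, shared); cb <- clade_sets(tr, shared)
    same <- length(ca) == length(cb) &&
      all(vapply(ca, function(s) any(vapply(cb, identical, TRUE, x = s)), TRUE))
    if (!same) stop("species trees conflict topologically on shared species")
    if (length(b) > length(a)) best <- tr
  }
  best
}
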