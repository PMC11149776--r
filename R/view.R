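# The view algebra: a view_state records which gene nodes and which taxa are
# collapsed for one or more families over a shared species tree.  All
# operations are pure (they return a new state) and idempotent where the
# interface says so.  Two invariants are maintained throughout:
#   * maximality: no collapsed gene node (or taxon) is a descendant of
#     another collapsed one;
#   * cascade: every gene node whose taxon lies within a collapsed taxon is
#     at or below some collapsed gene node.

#' Initialize a view over one or more families
#'
#' @param families a `reconciled_family` or list of them, all normalized and
#'   attached to the same species tree.
#' @param stree the shared `species_tree`; defaults to the first family's.
#' @param root_taxon optional taxon name: restrict the display to its
#'   subtree (gene nodes outside it, including losses, are pruned).
#' @return A `view_state` with empty collapse sets.
#' @export
init_view <- function(families, stree = NULL, root_taxon = NULL) {
  if (inherits(families, "reconciled_family")) families <- list(families)
  stopifnot(length(families) >= 1L)
  if (is.null(stree)) stree <- families[[1L]]$species_tree
  for (f in families) {
    if (!identical(f$species_tree$id, stree$id) ||
        !identical(f$species_tree$parent, stree$parent))
      stop("all families must share one species tree")
    if (!isTRUE(f$normalized))
      stop("family '", f$family_id, "' is not normalized; run normalize_family()")
  }
  rt <- NA_character_
  if (!is.null(root_taxon)) {
    st_resolve(stree, root_taxon)  # errors on unknown name
    rt <- root_taxon
    families <- lapply(families, prune_to_taxon, taxon = root_taxon)
  }
  ids <- vapply(families, `[[`, "", "family_id")
  if (anyDuplicated(ids)) stop("duplicate family ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  structure(list(
    families = stats::setNames(families, ids), stree = stree,
    collapsed = stats::setNames(rep(list(character(0)), length(ids)), ids),
    collapsed_taxa = character(0), depth_limit = NA_integer_,
    root_taxon = rt, clade_colors = character(0)),
    class = "view_state")
}

#' @export
print.view_state <- function(x, ...) {
  cat(sprintf("view_state: %d famil%s, %d visible column(s), %d collapsed taxa\n",
              length(x$families), if (length(x$families) == 1L) "y" else "ies",
              length(visible_columns(x)), length(x$collapsed_taxa)))
  invisible(x)
}

#' Restrict a normalized family to the subtree of a taxon
#'
#' Gene nodes whose taxon is disjoint from the target subtree (including
#' loss tips) are removed; unary speciation chains above it are spliced;
#' duplications above it that keep several surviving children are retained
#' with their taxon reassigned to the target.
#'
#' @param family normalized `reconciled_family`.
#' @param taxon species-tree node name.
#' @return The pruned family (still normalized).
#' @export
prune_to_taxon <- function(family, taxon) {
  st <- family$species_tree
  target <- st_resolve(st, taxon)
  rec <- function(n) {
    tx <- st_resolve(st, n$taxon)
    if (st_is_desc(st, tx, target)) return(n)              # wholly inside
    if (!st_is_desc(st, target, tx)) return(NULL)          # disjoint: drop
    kept <- Filter(Negate(is.null), lapply(n$children, rec))
    if (length(kept) == 0L) return(NULL)
    if (length(kept) == 1L) return(kept[[1L]])             # splice chain node
    n$children <- kept
    n$taxon <- st$name[target]                             # duplication above
    n
  }
  root <- rec(family$root)
  if (is.null(root))
    stop("family '", family$family_id, "' has no gene content within taxon '",
         taxon, "'")
  family$root <- root
  family
}

# --- internal helpers ------------------------------------------------------

subtree_dup_free <- function(node) {
  if (identical(node$event, "duplication")) return(FALSE)
  all(vapply(node$children, subtree_dup_free, TRUE))
}

taxon_hidden <- function(state, taxon_name) {
  # strictly inside a collapsed taxon?
  st <- state$stree
  v <- st_resolve(st, taxon_name)
  any(vapply(state$collapsed_taxa, function(ct) {
    c_ <- st_resolve(st, ct)
    c_ != v && st_is_desc(st, v, c_)
  }, TRUE))
}

in_collapsed_taxon <- function(state, taxon_name) {
  st <- state$stree
  v <- st_resolve(st, taxon_name)
  any(vapply(state$collapsed_taxa, function(ct)
    st_is_desc(st, v, st_resolve(st, ct)), TRUE))
}

# re-enforce the cascade invariant: topmost displayed gene nodes whose taxon
# lies within a collapsed taxon are added to the collapsed set
enforce_cascade <- function(state) {
  if (length(state$collapsed_taxa) == 0L) return(state)
  for (fid in names(state$families)) {
    fam <- state$families[[fid]]
    set <- state$collapsed[[fid]]
    rec <- function(n) {
      if (n$id %in% set) return(invisible(NULL))   # already a collapsed tip
      if (in_collapsed_taxon(state, n$taxon)) {
        set <<- c(setdiff(set, gn_ids(n)), n$id)   # drop collapsed descendants
        return(invisible(NULL))
      }
      for (ch in n$children) rec(ch)
    }
    rec(fam$root)
    state$collapsed[[fid]] <- set
  }
  state
}

#' Smart Collapse: collapse every maximal duplication-free subtree
#'
#' The resulting view is information-equivalent to the fully expanded gene
#' tree: collapsed subtrees are congruent with the species tree, and their
#' copy numbers remain readable from the profile rows.  Idempotent.
#'
#' @param state a `view_state`.
#' @return The updated state.
#' @export
smart_collapse <- function(state) {
  for (fid in names(state$families)) {
    fam <- state$families[[fid]]
    set <- character(0)
    rec <- function(n) {
      if (gn_is_tip(n)) return(invisible(NULL))
      if (subtree_dup_free(n)) set[[length(set) + 1L]] <<- n$id
      else for (ch in n$children) rec(ch)
    }
    rec(fam$root)
    state$collapsed[[fid]] <- set
  }
  enforce_cascade(state)
}

#' Collapse All: one profile row per family
#'
#' Every family is reduced to its root row; the profile then shows the
#' family-wide copy-number distribution.  Idempotent.
#'
#' @param state a `view_state`.
#' @return The updated state.
#' @export
collapse_all <- function(state) {
  for (fid in names(state$families))
    state$collapsed[[fid]] <- state$families[[fid]]$root$id
  state
}

#' Expand a collapsed node down to the next duplications
#'
#' The node is revealed together with the speciation chains leading to the
#' topmost duplications below it; those duplications, and every maximal
#' duplication-free subtree hanging off the revealed chains, stay collapsed.
#'
#' @param state a `view_state`.
#' @param family_id which family.
#' @param node_id the collapsed gene node to expand.
#' @return The updated state.
#' @export
expand_node <- function(state, family_id, node_id) {
  fam <- state$families[[family_id]]
  if (is.null(fam)) stop("unknown family: ", family_id)
  set <- state$collapsed[[family_id]]
  if (!node_id %in% set) {
    warning("node '", node_id, "' is not collapsed; nothing to expand")
    return(state)
  }
  node <- gn_find(fam$root, node_id)
  if (gn_is_tip(node)) return(state)               # a bare tip stays a tip
  set <- setdiff(set, node_id)
  frontier <- character(0)
  rec <- function(n) {
    for (ch in n$children) {
      if (gn_is_tip(ch)) next
      if (identical(ch$event, "duplication") || subtree_dup_free(ch))
        frontier[[length(frontier) + 1L]] <<- ch$id
      else rec(ch)
    }
  }
  rec(node)
  state$collapsed[[family_id]] <- c(set, frontier)
  enforce_cascade(state)
}

#' Collapse a displayed gene node into a single profile row
#'
#' @param state a `view_state`.
#' @param family_id which family.
#' @param node_id a currently displayed gene node (collapsing an extant leaf
#'   is allowed and yields a single-gene row).
#' @return The updated state.
#' @export
collapse_node <- function(state, family_id, node_id) {
  fam <- state$families[[family_id]]
  if (is.null(fam)) stop("unknown family: ", family_id)
  set <- state$collapsed[[family_id]]
  if (node_id %in% set) return(state)              # idempotent
  node <- gn_find(fam$root, node_id)
  if (is.null(node)) stop("unknown gene node: ", node_id)
  under <- any(vapply(set, function(cid) {
    cn <- gn_find(fam$root, cid)
    node_id %in% gn_ids(cn)
  }, TRUE))
  if (under) stop("node '", node_id, "' is already inside a collapsed subtree")
  state$collapsed[[family_id]] <- c(setdiff(set, gn_ids(node)), node_id)
  state
}

#' Collapse a taxon in the species tree
#'
#' The taxon's column replaces its descendants' columns and, in every
#' family, the topmost displayed gene nodes whose taxon lies within it are
#' collapsed (the cascade), so no gene-tree structure below the taxon stays
#' visible.  Profile values over the merged column become averages of
#' per-species in-paralog counts.
#'
#' @param state a `view_state`.
#' @param taxon internal species-tree node name, currently displayed.
#' @return The updated state.
#' @export
collapse_taxon <- function(state, taxon) {
  st <- state$stree
  v <- st_resolve(st, taxon)
  if (st_is_leaf(st, v))
    stop("'", taxon, "' is an extant species; nothing to collapse")
  if (taxon %in% state$collapsed_taxa) return(state)   # idempotent
  if (taxon_hidden(state, taxon))
    stop("taxon '", taxon, "' is not displayed (inside a collapsed taxon)")
  drop <- state$collapsed_taxa[vapply(state$collapsed_taxa, function(ct)
    st_is_desc(st, st_resolve(st, ct), v), TRUE)]
  state$collapsed_taxa <- c(setdiff(state$collapsed_taxa, drop), taxon)
  enforce_cascade(state)
}

#' Auto-collapse the species tree at a given depth
#'
#' Every internal species node at depth exactly `d` from the displayed root
#' (depth 0) is taxon-collapsed, hiding everything deeper.
#'
#' @param state a `view_state`.
#' @param d integer depth >= 0.
#' @return The updated state.
#' @export
auto_collapse_depth <- function(state, d) {
  stopifnot(d >= 0)
  st <- state$stree
  base <- if (is.na(state$root_taxon)) st$root else st_resolve(st, state$root_taxon)
  targets <- which(st$depth - st$depth[base] == d & !st_is_leaf(st, seq_along(st$id)))
  targets <- targets[vapply(targets, function(v) st_is_desc(st, v, base), TRUE)]
  for (v in targets) {
    if (!taxon_hidden(state, st$name[v]) && !(st$name[v] %in% state$collapsed_taxa))
      state <- collapse_taxon(state, st$name[v])
  }
  state$depth_limit <- as.integer(d)
  state
}

#' Visible profile columns
#'
#' The tips of the species tree after applying `root_taxon` and the
#' collapsed taxa, in species-tree left-to-right order.
#'
#' @param state a `view_state`.
#' @return Character vector of species-tree node names (one per column).
#' @export
visible_columns <- function(state) {
  st <- state$stree
  base <- if (is.na(state$root_taxon)) st$root else st_resolve(st, state$root_taxon)
  out <- character(0)
  rec <- function(v) {
    if (st$name[v] %in% state$collapsed_taxa || st_is_leaf(st, v)) {
      out[[length(out) + 1L]] <<- st$name[v]
    } else for (ch in st$children[[v]]) rec(ch)
  }
  rec(base)
  out
}

#' Displayed gene-tree tips, in drawing order
#'
#' Preorder traversal of the displayed gene tree; children are ordered by
#' the species-tree position of their taxon, with duplication co-children
#' tie-broken by descending extant-leaf count and then id.  One entry per
#' profile-matrix row.
#'
#' @param state a `view_state`.
#' @param family_id which family.
#' @return List of `gene_node`s (collapsed subfamily roots, extant leaves,
#'   loss tips).
#' @export
visible_tips <- function(state, family_id) {
  fam <- state$families[[family_id]]
  if (is.null(fam)) stop("unknown family: ", family_id)
  st <- state$stree
  set <- state$collapsed[[family_id]]
  tips <- list()
  rec <- function(n) {
    if (n$id %in% set || gn_is_tip(n)) {
      tips[[length(tips) + 1L]] <<- n
      return(invisible(NULL))
    }
    kids <- n$children
    pos <- vapply(kids, function(ch) st$leftmost[st_resolve(st, ch$taxon)],
                  integer(1))
    size <- vapply(kids, function(ch) sum(leaf_counts(ch)), integer(1))
    ids <- vapply(kids, `[[`, "", "id")
    for (ch in kids[order(pos, -size, ids)]) rec(ch)
  }
  rec(fam$root)
  tips
}

#' Displayed gene tree as a nested structure (for layout)
#'
#' Like [visible_tips()] but keeps the internal displayed nodes, with
#' children already in drawing order and a `collapsed` flag per node.
#'
#' @param state a `view_state`.
#' @param family_id which family.
#' @return Nested list mirroring the displayed gene tree.
#' @keywords internal
displayed_tree <- function(state, family_id) {
  fam <- state$families[[family_id]]
  st <- state$stree
  set <- state$collapsed[[family_id]]
  rec <- function(n) {
    if (n$id %in% set || gn_is_tip(n)) {
      return(list(node = n, collapsed = !gn_is_tip(n) || n$id %in% set,
                  children = list()))
    }
    kids <- n$children
    pos <- vapply(kids, function(ch) st$leftmost[st_resolve(st, ch$taxon)],
                  integer(1))
    size <- vapply(kids, function(ch) sum(leaf_counts(ch)), integer(1))
    ids <- vapply(kids, `[[`, "", "id")
    list(node = n, collapsed = FALSE,
         children = lapply(kids[order(pos, -size, ids)], rec))
  }
  rec(fam$root)
}

#' Assign display colors to species-tree clades
#'
#' @param state a `view_state`.
#' @param colors named character vector, taxon name -> "#rrggbb".
#' @return The updated state.
#' @export
set_clade_colors <- function(state, colors) {
  st_resolve(state$stree, names(colors))  # validate names
  bad <- !grepl("^#[0-9a-fA-F]{6}$", colors)
  if (any(bad)) stop("colors must be #rrggbb: ",
                     paste(colors[bad], collapse = ", "))
  state$clade_colors <- c(state$clade_colors[setdiff(names(state$clade_colors),
                                                     names(colors))], colors)
  state
}
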