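# Normalization against the species tree: make implied speciations explicit
# and attach loss tips, so that every speciation node's children map exactly
# onto the children of its taxon.  The normalized form is what the collapse
# engine and the profile matrix operate on.

implied_spec_id <- function(anchor_id, taxon_name) paste0(anchor_id, "@", taxon_name)

#' Insert implied speciation nodes
#'
#' On every gene-tree edge that skips species-tree levels, a chain of
#' speciation nodes is inserted, one per skipped species-tree node on the
#' path.  A duplication child whose extant span lies below the duplication's
#' taxon additionally gets a speciation at the duplication's taxon itself,
#' so that subfamily origins coincide with the duplication node's taxon.
#' Inserted node ids are `"<child_id>@<taxon>"`, deterministic across runs.
#'
#' @param family an annotated, event-labeled `reconciled_family`.
#' @return The family with implied speciations inserted.
#' @export
insert_implied_speciations <- function(family) {
  st <- family$species_tree

  chain_down <- function(child, taxa_idx) {
    # wrap `child` in speciation nodes at taxa_idx (top..bottom order)
    out <- child
    for (tx in rev(taxa_idx)) {
      out <- gene_node(implied_spec_id(child$id, st$name[tx]),
                       event = "speciation", taxon = st$name[tx],
                       children = list(out))
    }
    out
  }

  rec <- function(n) {
    if (length(n$children) == 0L) return(n)
    tx <- st_resolve(st, n$taxon)
    kind <- event_kind(n$event)
    n$children <- lapply(n$children, function(ch) {
      ch <- rec(ch)
      ctx <- st_resolve(st, ch$taxon)
      if (!st_is_desc(st, ctx, tx))
        stop("node '", ch$id, "' at taxon '", ch$taxon,
             "' is not within its parent's taxon '", n$taxon, "'",
             call. = FALSE)
      if (kind == "duplication") {
        if (ctx == tx) return(ch)
        # chain from the duplication's taxon down to (excluding) the child's
        path <- st_path(st, tx, ctx)                 # tx .. ctx inclusive
        chain_down(ch, path[-length(path)])
      } else {                                       # speciation / transfer
        if (ctx == tx) return(ch)                    # flagged by validation
        path <- st_path(st, tx, ctx)                 # tx, c1, ..., ctx
        skipped <- path[-c(1L, length(path))]        # strictly between
        if (length(skipped) == 0L) return(ch)
        chain_down(ch, skipped)
      }
    })
    n
  }
  family$root <- rec(family$root)
  family
}

#' Attach loss tips implied by the species tree
#'
#' Every speciation node at taxon t gains one loss leaf per child of t with
#' no gene child mapping into its subtree -- one tip per maximal lost clade,
#' labeled with the clade's taxon name.  Speciation children are ordered by
#' species-tree position for deterministic layout.
#'
#' @param family a family with implied speciations inserted.
#' @return The normalized family (`normalized = TRUE`).
#' @export
infer_losses <- function(family) {
  st <- family$species_tree
  rec <- function(n) {
    if (length(n$children) == 0L) return(n)
    n$children <- lapply(n$children, rec)
    if (event_kind(n$event) == "speciation") {
      tx <- st_resolve(st, n$taxon)
      covered <- vapply(n$children, function(ch) st_resolve(st, ch$taxon),
                        integer(1))
      for (c_ in setdiff(st$children[[tx]], covered)) {
        n$children[[length(n$children) + 1L]] <-
          gene_loss(paste0(n$id, "@loss@", st$name[c_]), taxon = st$name[c_],
                    label = st$name[c_])
      }
      # order children by the species-tree position of their taxon
      key <- vapply(n$children, function(ch)
        st$leftmost[st_resolve(st, ch$taxon)], integer(1))
      n$children <- n$children[order(key)]
    }
    n
  }
  family$root <- rec(family$root)
  family$normalized <- TRUE
  family
}

#' Normalize a family against its species tree
#'
#' [insert_implied_speciations()] followed by [infer_losses()].  Idempotent;
#' never changes [leaf_counts()] of any pre-existing node.
#'
#' @param family an annotated `reconciled_family`.
#' @return The normalized family.
#' @export
normalize_family <- function(family) infer_losses(insert_implied_speciations(family))

#' Contract a gene tree to its duplication skeleton
#'
#' The gene tree reduced to the root plus all duplication nodes, with
#' parent-child meaning nearest-duplication-ancestor.  This is the
#' information-complete compact view: everything in between is congruent
#' with the species tree.
#'
#' @param family a `reconciled_family`.
#' @return Nested list: `list(id, taxon, children = <list of the same>)`.
#' @export
duplication_skeleton <- function(family) {
  top_dups <- function(n) {
    # topmost duplication nodes at or below n's children
    out <- list()
    for (ch in n$children) {
      if (identical(ch$event, "duplication")) out[[length(out) + 1L]] <- ch
      else out <- c(out, top_dups(ch))
    }
    out
  }
  build <- function(n) {
    list(id = n$id, taxon = n$taxon,
         children = lapply(top_dups(n), build))
  }
  build(family$root)
}

# --- component decomposition (used by the simulator ground truth and the
#     loss-recovery checks) --------------------------------------------------

# Split a (pruned, not necessarily normalized) gene tree into subfamily
# components: the root plus every child lineage of every duplication node.
# Each component records its origin taxon, the extant species reached
# without crossing another duplication, and the taxa of the topmost nested
# duplications (its delegation endpoints).
family_components <- function(family) {
  st <- family$species_tree
  comps <- list()
  scan <- function(n) {
    # species + endpoint taxa in n's region (stop at duplications)
    if (identical(n$event, "leaf"))
      return(list(species = n$species, endpoints = character(0)))
    if (identical(n$event, "duplication"))
      return(list(species = character(0), endpoints = n$taxon))
    sp <- character(0); ep <- character(0)
    for (ch in n$children) {
      r <- scan(ch); sp <- c(sp, r$species); ep <- c(ep, r$endpoints)
    }
    list(species = unique(sp), endpoints = ep)
  }
  descend <- function(top, origin) {
    r <- if (identical(top$event, "duplication"))
      list(species = character(0), endpoints = top$taxon) else scan(top)
    # after normalization a component whose top sits below its origin taxon
    # is wrapped in an implied-speciation chain whose topmost node carries
    # the id "<top>@<origin>"; key components by that stable id
    key <- if (identical(origin, top$taxon)) top$id
           else implied_spec_id(top$id, origin)
    comps[[length(comps) + 1L]] <<-
      list(top_id = key, origin = origin, species = r$species,
           endpoints = r$endpoints)
    # recurse into every duplication reachable from this component
    into_dups <- function(n) {
      if (identical(n$event, "duplication")) {
        for (ch in n$children) descend(ch, n$taxon)
      } else {
        for (ch in n$children) into_dups(ch)
      }
    }
    into_dups(top)
  }
  descend(family$root, family$root$taxon)
  comps
}

# Maximal species clades within span(origin) not covered by any endpoint:
# covered = subtrees of extant member species and of delegated duplication
# taxa, plus the paths leading to them.
lost_clades_for_component <- function(st, comp) {
  anchors <- unique(c(
    if (length(comp$species)) st_resolve(st, comp$species) else integer(0),
    if (length(comp$endpoints)) st_resolve(st, comp$endpoints) else integer(0)))
  origin <- st_resolve(st, comp$origin)
  if (length(anchors) == 0L) return(character(0))
  lost <- character(0)
  rec <- function(v) {
    in_anchor <- any(vapply(anchors, function(a) st_is_desc(st, v, a), TRUE))
    if (in_anchor) return(invisible(NULL))      # delegated or extant member
    has_anchor <- any(vapply(anchors, function(a) st_is_desc(st, a, v), TRUE))
    if (!has_anchor) {                          # maximal uncovered clade
      lost[[length(lost) + 1L]] <<- st$name[v]
      return(invisible(NULL))
    }
    for (ch in st$children[[v]]) rec(ch)
  }
  rec(origin)
  sort(lost)
}

#' Observable lost clades per subfamily component
#'
#' For the root lineage and every duplication child lineage, the maximal
#' species-tree clades inside the lineage's origin span with no surviving
#' member and no delegated (nested-duplication) coverage.  Computed from the
#' species tree directly -- independent of the loss-insertion walk -- so it
#' doubles as the oracle for [infer_losses()].
#'
#' @param family a `reconciled_family` (pruned to survivors; normalization
#'   not required).
#' @return Named list, component top node id -> sorted character vector of
#'   lost clade taxon names.
#' @export
observable_losses <- function(family) {
  st <- family$species_tree
  comps <- family_components(family)
  out <- lapply(comps, function(cp) lost_clades_for_component(st, cp))
  stats::setNames(out, vapply(comps, `[[`, "", "top_id"))
}

#' Loss tips grouped by subfamily component
#'
#' Groups the loss leaves of a normalized family by their nearest enclosing
#' component (root lineage or duplication child lineage), for comparison
#' with [observable_losses()].
#'
#' @param family a normalized `reconciled_family`.
#' @return Named list, component top node id -> sorted taxon names of its
#'   loss tips.
#' @export
loss_tips_by_component <- function(family) {
  out <- list()
  descend <- function(top) {
    key <- top$id
    out[[key]] <<- character(0)
    region <- function(n) {
      if (identical(n$event, "loss")) {
        out[[key]] <<- c(out[[key]], n$taxon)
      } else if (identical(n$event, "duplication")) {
        for (ch in n$children) descend(ch)
      } else {
        for (ch in n$children) region(ch)
      }
    }
    if (identical(top$event, "duplication")) {
      for (ch in top$children) descend(ch)
      # a duplication top delegates everything; its own region is empty
    } else region(top)
    out[[key]] <<- sort(out[[key]])
  }
  descend(family$root)
  out
}
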