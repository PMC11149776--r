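# Reconciled gene trees: nested gene_node lists carrying an event label and
# a species-tree taxon assignment.  Taxa are stored by species-node name so
# that serialization is direct; resolution against the species_tree happens
# in the operations.

EVENTS <- c("leaf", "speciation", "duplication", "loss", "transfer")

# synonyms accepted on input (orthoXML-style and common shorthands)
EVENT_SYNONYMS <- c(
  leaf = "leaf", gene = "leaf", extant = "leaf",
  speciation = "speciation", spec = "speciation", S = "speciation",
  orthologGroup = "speciation",
  duplication = "duplication", dup = "duplication", D = "duplication",
  paralogGroup = "duplication",
  loss = "loss", L = "loss",
  transfer = "transfer", T = "transfer")

normalize_event <- function(e) {
  if (is.null(e) || is.na(e)) return(NA_character_)
  out <- EVENT_SYNONYMS[[e]]
  if (is.null(out)) stop("unrecognized event label: '", e, "'", call. = FALSE)
  out
}

# "transfer" is preserved on round-trip but behaves as a speciation
# throughout the view algebra (no dedicated layout semantics).
event_kind <- function(e) if (identical(e, "transfer")) "speciation" else e

#' Construct a gene-tree node
#'
#' @param id unique node id within the family.
#' @param event one of `"leaf"`, `"speciation"`, `"duplication"`, `"loss"`,
#'   `"transfer"` (or `NA` to be inferred later).
#' @param species extant species name (leaves only).
#' @param taxon species-tree node name (origin taxon); inferred by
#'   [annotate_taxa()] when `NA`.
#' @param label display label; defaults to gene id for leaves.
#' @param children list of child `gene_node`s.
#' @param extra named list of extra fields preserved on JSON round-trip.
#' @return A `gene_node`.
#' @export
gene_node <- function(id, event = NA, species = NA, taxon = NA, label = NA,
                      children = list(), extra = list()) {
  ev <- normalize_event(if (is.na(event)) NA else as.character(event))
  structure(list(id = as.character(id), event = ev,
                 species = as.character(species), taxon = as.character(taxon),
                 label = as.character(label), children = children,
                 extra = extra),
            class = "gene_node")
}

#' @rdname gene_node
#' @export
gene_leaf <- function(id, species, label = id, extra = list()) {
  gene_node(id, event = "leaf", species = species, taxon = species,
            label = label, extra = extra)
}

#' @rdname gene_node
#' @export
gene_loss <- function(id, taxon, label = taxon) {
  gene_node(id, event = "loss", taxon = taxon, label = label)
}

#' Assemble a reconciled gene family
#'
#' Binds a gene tree to its species tree and runs taxon annotation and
#' species-overlap event inference for nodes lacking explicit labels.
#'
#' @param family_id family identifier (e.g. a HOG id).
#' @param root the root `gene_node`.
#' @param stree the associated `species_tree`.
#' @param annotate run [annotate_taxa()] and [infer_events()] (default TRUE).
#' @return A `reconciled_family`.
#' @export
reconciled_family <- function(family_id, root, stree, annotate = TRUE) {
  fam <- structure(list(family_id = as.character(family_id), root = root,
                        species_tree = stree, normalized = FALSE),
                   class = "reconciled_family")
  if (annotate) fam <- infer_events(annotate_taxa(fam))
  fam
}

#' @export
print.reconciled_family <- function(x, ...) {
  cnt <- leaf_counts(x$root)
  cat(sprintf("reconciled_family '%s': %d genes in %d species%s\n",
              x$family_id, sum(cnt), length(cnt),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

# --- traversal helpers -----------------------------------------------------

gn_walk <- function(node, fn) {
  fn(node)
  for (ch in node$children) gn_walk(ch, fn)
  invisible(NULL)
}

gn_collect <- function(node, pred = function(n) TRUE) {
  out <- list()
  gn_walk(node, function(n) if (isTRUE(pred(n))) out[[length(out) + 1L]] <<- n)
  out
}

gn_find <- function(node, id) {
  if (identical(node$id, id)) return(node)
  for (ch in node$children) {
    hit <- gn_find(ch, id)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

gn_ids <- function(node) vapply(gn_collect(node), `[[`, "", "id")

gn_is_tip <- function(node) event_kind(node$event) %in% c("leaf", "loss")

# extant species names under a node (unique)
gn_species_set <- function(node) {
  if (identical(node$event, "leaf")) return(node$species)
  unique(unlist(lapply(node$children, gn_species_set), use.names = FALSE))
}

#' Per-species extant gene counts under a node
#'
#' The brute-force copy-number oracle: for every extant species, the number
#' of `leaf` descendants (including the node itself) assigned to it.
#' Species with zero copies are absent from the result.
#'
#' @param node a `gene_node` (or a `reconciled_family`, whose root is used).
#' @return Named integer vector, species name to count.
#' @export
leaf_counts <- function(node) {
  if (inherits(node, "reconciled_family")) node <- node$root
  sp <- character(0)
  rec <- function(n) {
    if (identical(n$event, "leaf")) sp[[length(sp) + 1L]] <<- n$species
    for (ch in n$children) rec(ch)
  }
  rec(node)
  if (length(sp) == 0L) return(stats::setNames(integer(0), character(0)))
  tb <- table(sp)
  stats::setNames(as.integer(tb), names(tb))
}

# --- taxon annotation ------------------------------------------------------

#' Annotate gene-tree nodes with species-tree taxa
#'
#' Every node receives `taxon` = the LCA of the species of its extant
#' descendant leaves.  Explicit annotations (and the taxa of loss nodes) are
#' kept.  Idempotent.
#'
#' @param family a `reconciled_family`.
#' @param stree species tree; defaults to the family's.
#' @return The annotated family.
#' @export
annotate_taxa <- function(family, stree = family$species_tree) {
  st <- stree
  rec <- function(n) {
    if (identical(n$event, "leaf") ||
        (length(n$children) == 0L && is.na(n$event) && !is.na(n$species))) {
      if (is.na(n$species))
        stop("leaf node '", n$id, "' lacks a species", call. = FALSE)
      if (!n$species %in% names(st$index))
        stop("leaf '", n$id, "': unknown species name '", n$species, "'",
             call. = FALSE)
      n$event <- "leaf"
      n$taxon <- n$species
      return(n)
    }
    if (identical(n$event, "loss")) {
      if (is.na(n$taxon))
        stop("loss node '", n$id, "' lacks a taxon", call. = FALSE)
      if (!n$taxon %in% names(st$index))
        stop("loss '", n$id, "': unknown taxon name '", n$taxon, "'",
             call. = FALSE)
      return(n)
    }
    n$children <- lapply(n$children, rec)
    if (is.na(n$taxon)) {
      sp <- unique(unlist(lapply(n$children, gn_species_set), use.names = FALSE))
      if (length(sp) == 0L)
        stop("node '", n$id,
             "' has no extant descendants and no explicit taxon", call. = FALSE)
      n$taxon <- st$name[st_lca(st, st_resolve(st, sp))]
    } else if (!n$taxon %in% names(st$index)) {
      stop("node '", n$id, "': unknown taxon name '", n$taxon, "'",
           call. = FALSE)
    }
    n
  }
  family$root <- rec(family$root)
  family
}

#' Label internal nodes as duplication or speciation by species overlap
#'
#' An unlabeled internal node becomes a `duplication` iff the extant-species
#' sets of at least two of its children intersect, else a `speciation`.
#' Pre-existing labels are preserved.
#'
#' @param family a `reconciled_family` with taxa annotated.
#' @return The labeled family.
#' @export
infer_events <- function(family) {
  rec <- function(n) {
    if (length(n$children) == 0L) {
      if (is.na(n$event)) n$event <- if (!is.na(n$species)) "leaf" else "loss"
      return(n)
    }
    n$children <- lapply(n$children, rec)
    if (is.na(n$event)) {
      sets <- lapply(n$children, gn_species_set)
      overlap <- FALSE
      if (length(sets) >= 2L) {
        for (i in seq_len(length(sets) - 1L)) {
          for (j in seq.int(i + 1L, length(sets))) {
            if (length(intersect(sets[[i]], sets[[j]])) > 0L) overlap <- TRUE
          }
        }
      }
      n$event <- if (overlap) "duplication" else "speciation"
    }
    n
  }
  family$root <- rec(family$root)
  family
}

# --- validation ------------------------------------------------------------

#' Check the gene-tree/species-tree consistency contract
#'
#' Walks the gene tree and reports every violation (never throws): unknown
#' taxa, malformed tips, child taxa that are not within the parent's taxon,
#' speciation children mapping into the same species-tree child, and -- for
#' normalized families -- the exact speciation/loss/duplication shape.
#'
#' @param family a `reconciled_family` with taxa and events annotated.
#' @param stree species tree; defaults to the family's.
#' @return A `validation_report`: data.frame of (node_id, rule, message)
#'   with attribute/field `ok`.
#' @export
validate_reconciliation <- function(family, stree = family$species_tree) {
  st <- stree
  viol <- list()
  add <- function(id, rule, msg)
    viol[[length(viol) + 1L]] <<- data.frame(node_id = id, rule = rule,
                                             message = msg,
                                             stringsAsFactors = FALSE)
  seen_ids <- character(0)
  known <- function(tx) !is.na(tx) && tx %in% names(st$index)

  rec <- function(n, parent) {
    if (n$id %in% seen_ids) add(n$id, "duplicate_id", "node id is not unique")
    seen_ids <<- c(seen_ids, n$id)
    kind <- event_kind(n$event)
    if (!known(n$taxon)) {
      add(n$id, "unknown_taxon",
          paste0("taxon '", n$taxon, "' is not in the species tree"))
      return(invisible(NULL))
    }
    tx <- st_resolve(st, n$taxon)
    if (kind == "leaf") {
      if (length(n$children) > 0L) add(n$id, "leaf_shape", "leaf has children")
      if (is.na(n$species) || !identical(n$species, n$taxon) ||
          !st_is_leaf(st, tx))
        add(n$id, "leaf_shape", "leaf taxon must equal its extant species")
    } else if (kind == "loss") {
      if (length(n$children) > 0L) add(n$id, "loss_shape", "loss has children")
    } else {
      if (length(n$children) == 0L)
        add(n$id, "empty_internal", paste0(kind, " node has no children"))
    }
    if (!is.null(parent) && known(parent$taxon)) {
      ptx <- st_resolve(st, parent$taxon)
      if (!st_is_desc(st, tx, ptx)) {
        rule <- if (st_is_desc(st, ptx, tx)) "ancestor_taxon" else "disjoint_taxon"
        add(n$id, rule, paste0("child taxon '", n$taxon,
                               "' is not within parent taxon '",
                               parent$taxon, "'"))
      }
    }
    if (kind == "speciation" && length(n$children) > 0L) {
      # children must map into distinct children of the node's taxon
      slot <- vapply(n$children, function(ch) {
        if (!known(ch$taxon)) return(NA_integer_)
        ctx <- st_resolve(st, ch$taxon)
        if (identical(ctx, tx)) return(-1L)
        hit <- st$children[[tx]][vapply(st$children[[tx]], function(c_)
          st_is_desc(st, ctx, c_), TRUE)]
        if (length(hit) == 1L) hit else NA_integer_
      }, integer(1))
      if (any(slot == -1L, na.rm = TRUE))
        add(n$id, "speciation_child_same_taxon",
            "speciation child maps to the speciation's own taxon")
      dup_slots <- slot[!is.na(slot) & slot > 0L]
      if (anyDuplicated(dup_slots))
        add(n$id, "sibling_overlap",
            "sibling lineages map to same species child under speciation")
      if (isTRUE(family$normalized)) {
        bad <- vapply(n$children, function(ch)
          known(ch$taxon) && !st_resolve(st, ch$taxon) %in% st$children[[tx]],
          TRUE)
        if (any(bad))
          add(n$id, "speciation_children_map",
              "normalized speciation child is not a direct child of the taxon")
        covered <- slot[!is.na(slot) & slot > 0L]
        missing <- setdiff(st$children[[tx]], covered)
        if (length(missing) > 0L)
          add(n$id, "missing_loss",
              paste0("no child (gene or loss) for species-tree child: ",
                     paste(st$name[missing], collapse = ", ")))
      }
    }
    if (kind == "duplication" && isTRUE(family$normalized)) {
      if (length(n$children) < 2L)
        add(n$id, "duplication_arity", "duplication has fewer than 2 children")
      for (ch in n$children) {
        if (known(ch$taxon) && !identical(ch$taxon, n$taxon))
          add(n$id, "duplication_children_taxon",
              paste0("duplication child '", ch$id,
                     "' is at taxon '", ch$taxon, "', expected '", n$taxon, "'"))
      }
    }
    for (ch in n$children) rec(ch, n)
  }
  rec(family$root, NULL)

  violations <- if (length(viol)) do.call(rbind, viol)
    else data.frame(node_id = character(0), rule = character(0),
                    message = character(0), stringsAsFactors = FALSE)
  structure(list(violations = violations, ok = nrow(violations) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("reconciliation OK: no violations\n")
  else {
    cat("reconciliation FAILED:", nrow(x$violations), "violation(s)\n")
    print(x$violations)
  }
  invisible(x)
}
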