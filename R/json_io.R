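# Native JSON dialect for reconciled families.
#
# A family document is
#   {"family_id": "...", "root": <node>}
# (a bare node is also accepted) where each node is
#   {"id": "...", "event": "leaf|speciation|duplication|loss|transfer",
#    "taxon": "<species-tree node name>", "species": "<extant species>",
#    "label": "...", "children": [<node>, ...]}
# "taxon"/"event" may be omitted and are then inferred (LCA annotation,
# species-overlap labeling).  Unknown fields are preserved on round-trip.
# Serialization is canonical: keys sorted, child order preserved, so output
# is byte-identical across runs.

KNOWN_NODE_FIELDS <- c("id", "event", "taxon", "species", "label", "children")

#' Read a gene family from its JSON document
#'
#' @param text JSON string, or path of a file holding one.
#' @param stree the associated `species_tree`.
#' @return A validated, taxon-annotated `reconciled_family` (not yet
#'   normalized; see [normalize_family()]).
#' @export
family_from_json <- function(text, stree) {
  if (length(text) == 1L && !grepl("[{]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  family_id <- "family"
  node_doc <- doc
  if (!is.null(doc$root)) {
    node_doc <- doc$root
    if (!is.null(doc$family_id)) family_id <- doc$family_id
  }
  seen <- new.env(parent = emptyenv())
  build <- function(d) {
    if (is.null(d$id)) stop("JSON node without an 'id'", call. = FALSE)
    id <- as.character(d$id)
    if (!is.null(seen[[id]])) stop("duplicate node id in JSON: '", id, "'",
                                   call. = FALSE)
    assign(id, TRUE, envir = seen)
    ev <- if (is.null(d$event)) NA_character_ else normalize_event(d$event)
    sp <- if (is.null(d$species)) NA_character_ else as.character(d$species)
    if (!is.na(sp) && !sp %in% names(stree$index))
      stop("unknown species name in JSON: '", sp, "' (node '", id, "')",
           call. = FALSE)
    tx <- if (is.null(d$taxon)) NA_character_ else as.character(d$taxon)
    if (!is.na(tx) && !tx %in% names(stree$index))
      stop("unknown taxon name in JSON: '", tx, "' (node '", id, "')",
           call. = FALSE)
    extra <- d[setdiff(names(d), KNOWN_NODE_FIELDS)]
    gene_node(id, event = if (is.na(ev)) NA else ev, species = sp, taxon = tx,
              label = if (is.null(d$label)) NA_character_
                      else as.character(d$label),
              children = lapply(d$children, build), extra = extra)
  }
  root <- build(node_doc)
  reconciled_family(family_id, root, stree, annotate = TRUE)
}

#' Serialize a gene family to canonical JSON
#'
#' Keys are sorted and child order preserved, so the output is stable
#' across runs and `family_from_json(family_to_json(f))` is the identity
#' on the model.
#'
#' @param family a `reconciled_family`.
#' @return A JSON string.
#' @export
family_to_json <- function(family) {
  to_list <- function(n) {
    out <- list(id = n$id)
    if (!is.na(n$event)) out$event <- n$event
    if (!is.na(n$label)) out$label <- n$label
    if (!is.na(n$species)) out$species <- n$species
    if (!is.na(n$taxon)) out$taxon <- n$taxon
    if (length(n$children) > 0L) out$children <- lapply(n$children, to_list)
    out <- c(out, n$extra)
    out[order(names(out))]
  }
  doc <- list(family_id = family$family_id, root = to_list(family$root))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' Write a family's JSON document to a file
#'
#' @param family a `reconciled_family`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_family_json <- function(family, path) {
  writeLines(family_to_json(family), path)
  invisible(path)
}

#' Structural equality of two families (tree isomorphism with labels)
#'
#' Compares id, event, taxon, species, label and child order recursively;
#' used for round-trip checks.
#'
#' @param a,b `reconciled_family` objects.
#' @return TRUE/FALSE.
#' @export
family_identical <- function(a, b) {
  eq <- function(x, y) {
    same <- identical(x$id, y$id) && identical(x$event, y$event) &&
      identical(x$taxon, y$taxon) && identical(x$species, y$species) &&
      length(x$children) == length(y$children)
    if (!same) return(FALSE)
    lx <- if (is.na(x$label)) x$id else x$label
    ly <- if (is.na(y$label)) y$id else y$label
    if (!identical(lx, ly)) return(FALSE)
    for (i in seq_along(x$children))
      if (!eq(x$children[[i]], y$children[[i]])) return(FALSE)
    TRUE
  }
  identical(a$family_id, b$family_id) && eq(a$root, b$root)
}
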