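# Network adapters for public gene-family resources, isolated behind a disk
# cache so that everything downstream (and the whole test suite) runs
# offline.  A cached entry is a JSON bundle
#   {"species_newick": "...", "family": <native family document>}
# written the first time an identifier is fetched.

oma_api_base <- "https://omabrowser.org/api"
panther_api_base <- "https://pantherdb.org/services/oai/pantherdb"

cache_path <- function(cache_dir, source, family_id) {
  file.path(cache_dir, paste0(source, "-", gsub("[^A-Za-z0-9_.:-]", "_",
                                                family_id), ".json"))
}

#' Fetch one or more gene families by identifier
#'
#' Resolves each identifier against the local cache first; only on a miss
#' is the corresponding public API contacted, and the normalized response
#' is then written back to the cache so repeated calls are offline.  When
#' several identifiers are given their species trees are merged by name
#' ([merge_species_trees()]).
#'
#' @param source `"oma"` (HOG ids) or `"panther"` (family ids).
#' @param family_id character vector of family identifiers.
#' @param cache_dir directory for cached responses (created if needed).
#' @param offline never attempt network access (default FALSE).
#' @return `list(families = <list of reconciled_family>, species_tree = ...)`.
#' @export
fetch_family <- function(source = c("oma", "panther"), family_id, cache_dir,
                         offline = FALSE) {
  source <- match.arg(source)
  stopifnot(length(family_id) >= 1L, all(nzchar(family_id)))
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)

  bundles <- lapply(family_id, function(id) {
    path <- cache_path(cache_dir, source, id)
    if (!file.exists(path)) {
      if (offline)
        stop("'", id, "' is not cached (looked for ", path,
             ") and offline mode is on", call. = FALSE)
      download_family_bundle(source, id, path)
    }
    jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"),
                       simplifyVector = FALSE)
  })

  trees <- lapply(bundles, function(b) read_species_newick(b$species_newick))
  stree <- merge_species_trees(trees)
  fams <- lapply(seq_along(bundles), function(i) {
    family_from_json(jsonlite::toJSON(bundles[[i]]$family, auto_unbox = TRUE,
                                      digits = NA),
                     stree)
  })
  list(families = fams, species_tree = stree)
}

# Live path: download the service response, convert it to the native bundle
# and cache it.  Targets the API shapes documented at the time of writing;
# errors carry the identifier and cache path so a user can drop a bundle in
# place by hand.
download_family_bundle <- function(source, id, path) {
  fetch <- function(url) {
    tryCatch(paste(readLines(url, warn = FALSE), collapse = "\n"),
             error = function(e)
               stop("fetching '", id, "' from ", source, " failed (",
                    conditionMessage(e), "); to work offline, place a bundle at ",
                    path, call. = FALSE))
  }
  if (source == "oma") {
    # HOG as orthoXML + induced species taxonomy as newick
    xml <- fetch(paste0(oma_api_base, "/hog/", utils::URLencode(id),
                        "/orthoxml/"))
    doc <- xml2::read_xml(xml); xml2::xml_ns_strip(doc)
    sp <- vapply(xml2::xml_find_all(doc, ".//species"),
                 function(s) xml2::xml_attr(s, "name"), "")
    nwk <- fetch(paste0(oma_api_base, "/taxonomy/?type=newick&members=",
                        utils::URLencode(paste(sp, collapse = ","),
                                         reserved = TRUE)))
    nwk <- jsonlite::fromJSON(nwk)$newick
    stree <- read_species_newick(nwk)
    fam <- family_from_orthoxml(xml, stree, family_id = id)
  } else {
    raw <- fetch(paste0(panther_api_base, "/treeinfo?family=",
                        utils::URLencode(id, reserved = TRUE)))
    parsed <- panther_tree_to_family(raw, id)
    stree <- parsed$species_tree
    fam <- parsed$family
  }
  bundle <- list(species_newick = species_newick(stree, with_lengths = FALSE),
                 family = jsonlite::fromJSON(family_to_json(fam),
                                             simplifyVector = FALSE))
  writeLines(jsonlite::toJSON(bundle, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Convert a PANTHER treeinfo response to the internal model
#'
#' Understands the `search$tree_topology$annotation_node` JSON shape:
#' nested `children$annotation_node` lists with `event_type`
#' ("SPECIATION"/"DUPLICATION"/...), `organism`/`species` on leaves and
#' optional `gene_id`/`accession` labels.  The species tree is taken as the
#' gene tree's own speciation scaffold (PANTHER trees embed their taxonomy);
#' imported event scenarios are taken verbatim.
#'
#' @param text PANTHER treeinfo JSON.
#' @param family_id id for the family.
#' @return `list(family = <reconciled_family>, species_tree = ...)`.
#' @export
panther_tree_to_family <- function(text, family_id = "panther") {
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  top <- doc$search$tree_topology$annotation_node
  if (is.null(top)) stop("unrecognized PANTHER treeinfo document",
                         call. = FALSE)
  counter <- 0L
  species_seen <- character(0)
  build <- function(d) {
    kids <- d$children$annotation_node
    if (is.null(kids)) kids <- list()
    if (!is.null(kids$accession) || !is.null(kids$event_type) ||
        !is.null(kids$children)) kids <- list(kids)   # single-node object
    if (length(kids) == 0L) {
      sp <- d$organism
      if (is.null(sp)) sp <- d$species
      if (is.null(sp)) stop("PANTHER leaf without an organism", call. = FALSE)
      sp <- gsub("[ ,():;]", "_", sp)
      species_seen <<- unique(c(species_seen, sp))
      lab <- d$gene_id
      if (is.null(lab)) lab <- d$accession
      counter <<- counter + 1L
      if (is.null(lab)) lab <- paste0("g", counter)
      return(gene_leaf(as.character(lab), species = sp))
    }
    ev <- d$event_type
    ev <- if (is.null(ev)) NA_character_
          else switch(toupper(ev), DUPLICATION = "duplication",
                      SPECIATION = "speciation",
                      HORIZ_TRANSFER = "transfer", NA_character_)
    counter <<- counter + 1L
    gene_node(paste0("n", counter), event = ev,
              children = lapply(kids, build))
  }
  root <- build(top)
  # species tree: the speciation scaffold of the gene tree itself
  scaffold <- function(n) {
    if (identical(n$event, "leaf")) return(n$species)
    sub <- lapply(n$children, scaffold)
    sub <- sub[!vapply(sub, is.null, TRUE)]
    if (identical(n$event, "duplication")) {
      if (length(sub) == 0L) return(NULL)
      return(sub[[1L]])                       # copies share one taxonomy
    }
    if (length(sub) == 0L) return(NULL)
    if (length(sub) == 1L) return(sub[[1L]])
    paste0("(", paste(unlist(sub), collapse = ","), ")")
  }
  nwk <- paste0(scaffold(root), ";")
  stree <- read_species_newick(nwk)
  list(family = reconciled_family(family_id, root, stree, annotate = TRUE),
       species_tree = stree)
}
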