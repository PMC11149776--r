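# orthoXML reader (read-only): orthologGroup -> speciation, paralogGroup ->
# duplication, geneRef -> extant leaf with the species of its declaration.
# Taxa are then annotated by LCA and the events validated against the
# species tree.

#' Read a gene family from an orthoXML document
#'
#' @param xml orthoXML string, or path of a file holding one.
#' @param stree the associated `species_tree`; species names in the XML must
#'   resolve against it.
#' @param family_id id for the resulting family; defaults to the top
#'   group's `id` attribute, else `"orthoxml"`.
#' @return A `reconciled_family` (annotated, not normalized).
#' @export
family_from_orthoxml <- function(xml, stree, family_id = NULL) {
  doc <- xml2::read_xml(xml)   # accepts a string or a file path
  xml2::xml_ns_strip(doc)

  gene_species <- character(0)   # internal gene id -> species name
  gene_prot <- character(0)      # internal gene id -> protId/geneId label
  for (sp in xml2::xml_find_all(doc, ".//species")) {
    sp_name <- xml2::xml_attr(sp, "name")
    if (!sp_name %in% names(stree$index))
      stop("orthoXML species '", sp_name, "' is not in the species tree",
           call. = FALSE)
    for (g in xml2::xml_find_all(sp, ".//gene")) {
      gid <- xml2::xml_attr(g, "id")
      lab <- xml2::xml_attr(g, "protId")
      if (is.na(lab)) lab <- xml2::xml_attr(g, "geneId")
      if (is.na(lab)) lab <- gid
      gene_species[[gid]] <- sp_name
      gene_prot[[gid]] <- lab
    }
  }

  groups <- xml2::xml_find_first(doc, ".//groups")
  if (inherits(groups, "xml_missing"))
    stop("orthoXML document has no <groups> section", call. = FALSE)
  top <- xml2::xml_find_first(groups, "./orthologGroup|./paralogGroup")
  if (inherits(top, "xml_missing"))
    stop("orthoXML <groups> section is empty", call. = FALSE)

  counter <- 0L
  build <- function(el) {
    nm <- xml2::xml_name(el)
    if (nm == "geneRef") {
      gid <- xml2::xml_attr(el, "id")
      sp <- gene_species[gid]
      if (is.na(sp) || is.null(sp))
        stop("geneRef to undeclared gene id '", gid, "'", call. = FALSE)
      return(gene_leaf(unname(gene_prot[gid]), species = unname(sp)))
    }
    if (nm %in% c("orthologGroup", "paralogGroup")) {
      counter <<- counter + 1L
      kids <- xml2::xml_find_all(
        el, "./orthologGroup|./paralogGroup|./geneRef")
      if (length(kids) == 0L)
        stop("empty ", nm, " in orthoXML", call. = FALSE)
      return(gene_node(
        paste0("n", counter),
        event = if (nm == "orthologGroup") "speciation" else "duplication",
        children = lapply(kids, build)))
    }
    stop("unexpected orthoXML element <", nm, ">", call. = FALSE)
  }
  root <- build(top)
  if (is.null(family_id)) {
    family_id <- xml2::xml_attr(top, "id")
    if (is.na(family_id)) family_id <- "orthoxml"
  }
  reconciled_family(family_id, root, stree, annotate = TRUE)
}
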