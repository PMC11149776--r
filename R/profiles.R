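# Phylogenetic-profile matrix for a view state.  Each cell is a copy-number
# value (exact rational: integer numerator over the number of averaged
# species), a loss-zero, or an outgroup-empty.  Rendering rounds for
# display; all internal arithmetic stays exact.

#' Compute one profile row for a displayed tip
#'
#' The row's span is the set of extant species under the tip's origin taxon
#' (where the subfamily arose; for a loss tip its lost clade, for an extant
#' leaf its species).  For each visible column u with extant leaf set L(u):
#' columns disjoint from the span are OUTGROUP; otherwise the value is the
#' mean in-paralog count over L(u) within the span (species lost under the
#' tip contribute 0), LOST when that mean is zero.
#'
#' @param tip a displayed `gene_node` (see [visible_tips()]).
#' @param state the `view_state`.
#' @param columns visible columns; defaults to [visible_columns()].
#' @return A `profile_row`: list with `tip_id`, `label`, `origin_taxon`,
#'   and per-column vectors `kind` ("COUNT"/"LOST"/"OUTGROUP"), `num`,
#'   `den`, `value`.
#' @export
profile_row <- function(tip, state, columns = visible_columns(state)) {
  st <- state$stree
  origin <- st_resolve(st, tip$taxon)
  span <- st_species_names_under(st, origin)
  counts <- leaf_counts(tip)
  nc <- length(columns)
  kind <- character(nc); num <- integer(nc); den <- integer(nc)
  for (j in seq_len(nc)) {
    u <- st_resolve(st, columns[[j]])
    I <- intersect(st_species_names_under(st, u), span)
    if (length(I) == 0L) {
      kind[j] <- "OUTGROUP"; num[j] <- NA_integer_; den[j] <- NA_integer_
    } else {
      s <- sum(counts[I], na.rm = TRUE)      # absent species count as 0
      g <- gcd_int(s, length(I))
      num[j] <- as.integer(s / g); den[j] <- as.integer(length(I) / g)
      kind[j] <- if (s == 0L) "LOST" else "COUNT"
    }
  }
  structure(list(
    tip_id = tip$id, label = tip_label(tip, st),
    origin_taxon = st$name[origin], kind = kind, num = num, den = den,
    value = ifelse(kind == "OUTGROUP", NA_real_, num / den)),
    class = "profile_row")
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0L) { t <- b; b <- a %% b; a <- t }
  max(a, 1L)
}

# display label per tip class: gene id for leaves, taxon name for losses,
# subfamily label (or id) for collapsed nodes
tip_label <- function(tip, st) {
  if (identical(tip$event, "leaf")) {
    if (!is.na(tip$label)) tip$label else tip$id
  } else if (identical(tip$event, "loss")) {
    st$name[st_resolve(st, tip$taxon)]
  } else {
    if (!is.na(tip$label)) tip$label else tip$id
  }
}

#' Compute the full profile matrix for a view state
#'
#' Rows are the displayed tips of every family (in family input order),
#' over the shared visible columns; `vmax` is the largest COUNT value, used
#' for heatmap shading.
#'
#' @param state a `view_state`.
#' @return A `profile_matrix`: list with `rows` (each a `profile_row` plus
#'   `family_id`), `columns` (taxon names), `vmax`.
#' @export
profile_matrix <- function(state) {
  columns <- visible_columns(state)
  rows <- list()
  for (fid in names(state$families)) {
    for (tip in visible_tips(state, fid)) {
      r <- profile_row(tip, state, columns)
      r$family_id <- fid
      rows[[length(rows) + 1L]] <- r
    }
  }
  vals <- unlist(lapply(rows, function(r) r$value[r$kind == "COUNT"]))
  structure(list(rows = rows, columns = columns,
                 vmax = if (length(vals)) max(vals) else 0),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d row(s) x %d column(s), vmax = %s\n",
              length(x$rows), length(x$columns), format(x$vmax)))
  print(as.data.frame(x))
  invisible(x)
}

#' Profile matrix as a data frame
#'
#' One row per displayed tip, one column per visible taxon.  COUNT cells
#' are numeric, LOST cells 0, OUTGROUP cells `NA`.
#'
#' @param x a `profile_matrix`.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return A data.frame with columns `family`, `tip`, `label`, `taxon`
#'   followed by the species columns.
#' @export
as.data.frame.profile_matrix <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  meta <- data.frame(
    family = vapply(x$rows, `[[`, "", "family_id"),
    tip = vapply(x$rows, `[[`, "", "tip_id"),
    label = vapply(x$rows, `[[`, "", "label"),
    taxon = vapply(x$rows, `[[`, "", "origin_taxon"),
    stringsAsFactors = FALSE)
  vals <- do.call(rbind, lapply(x$rows, function(r)
    ifelse(r$kind == "LOST", 0, r$value)))
  colnames(vals) <- x$columns
  cbind(meta, as.data.frame(vals, optional = TRUE))
}

#' Export a profile matrix as tab-separated values
#'
#' LOST cells are written as `0`, OUTGROUP cells as the empty string;
#' integers are written bare.
#'
#' @param matrix a `profile_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(matrix, path) {
  fmt <- function(r) vapply(seq_along(r$kind), function(j) {
    switch(r$kind[j],
           OUTGROUP = "",
           LOST = "0",
           COUNT = format_count(r$num[j] / r$den[j]))
  }, "")
  lines <- c(
    paste(c("family", "tip", "label", "taxon", matrix$columns),
          collapse = "\t"),
    vapply(matrix$rows, function(r)
      paste(c(r$family_id, r$tip_id, r$label, r$origin_taxon, fmt(r)),
            collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

# bare integers; otherwise full precision (display rounding is render-side)
format_count <- function(v) {
  if (v == round(v)) sprintf("%d", as.integer(round(v)))
  else format(v, digits = 15)
}
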