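# Deterministic static output: the tri-panel layout (species tree on top,
# gene tree on the left, profile heatmap in the matrix) as SVG 1.1, plus a
# self-contained HTML page embedding the serialized view.  Rendering is a
# pure function of (state, matrix): identical input gives identical bytes.

render_config <- function(cell_w = 26, cell_h = 20, sp_level_h = 22,
                          indent = 16, family_gap = 10, label_px = 7,
                          ramp_color = "#08306b", max_branch_width = 8) {
  list(cell_w = cell_w, cell_h = cell_h, sp_level_h = sp_level_h,
       indent = indent, family_gap = family_gap, label_px = label_px,
       ramp_color = ramp_color, max_branch_width = max_branch_width)
}

#' Heatmap shading intensity for a copy-number value
#'
#' Log-scaled so lineage-specific expansions stay distinguishable when one
#' row carries extreme counts: `log2(1+value)/log2(1+vmax)`, clipped to 1;
#' zero (and LOST) cells map to 0.
#'
#' @param value nonnegative copy number(s).
#' @param vmax matrix-wide maximum COUNT value.
#' @return Intensity in `[0, 1]`, same length as `value`.
#' @export
shade <- function(value, vmax) {
  value <- pmax(value, 0)
  ifelse(value <= 0 | vmax <= 0, 0,
         pmin(1, log2(1 + value) / log2(1 + vmax)))
}

#' Branch thickness for a (collapsed) subtree
#'
#' Grows with the number of extant genes underneath: `1 + log2(n)`, capped.
#'
#' @param n_leaves number of extant leaves (>= 1).
#' @param cap maximum width (default 8).
#' @return Width in user units.
#' @export
branch_width <- function(n_leaves, cap = 8) {
  pmin(1 + log2(pmax(n_leaves, 1)), cap)
}

#' Compute the drawing model for a view state
#'
#' Positions columns from [visible_columns()] order, rows from the matrix
#' row order, and lays out the species tree above the matrix and each
#' family's displayed gene tree to its left.  Per-tip labels follow the
#' standard convention (subfamily label for collapsed nodes, gene id for
#' leaves, taxon name for losses); each row is annotated on the right with
#' its origin taxon.
#'
#' @param state a `view_state`.
#' @param matrix its `profile_matrix` (defaults to computing it).
#' @param config geometry options from `render_config()`.
#' @return A `render_model` (lists of data frames with coordinates).
#' @export
layout_view <- function(state, matrix = profile_matrix(state),
                        config = render_config()) {
  st <- state$stree
  cf <- config
  cols <- matrix$columns
  nc <- length(cols)
  rows <- matrix$rows

  # --- left panel: displayed gene trees, measured first ---------------------
  fam_ids <- names(state$families)
  trees <- lapply(fam_ids, function(fid) displayed_tree(state, fid))
  tree_depth <- function(t) if (length(t$children) == 0L) 0L
    else 1L + max(vapply(t$children, tree_depth, 0L))
  max_depth <- if (length(trees)) max(vapply(trees, tree_depth, 0L)) else 0L
  labels <- vapply(rows, `[[`, "", "label")
  label_w <- (max(c(4L, nchar(labels))) + 1L) * cf$label_px
  gene_x0 <- 10
  matrix_x0 <- gene_x0 + (max_depth + 1L) * cf$indent + label_w + 8

  # --- top panel: species tree over the visible columns ---------------------
  base <- if (is.na(state$root_taxon)) st$root else st_resolve(st, state$root_taxon)
  vis_depth <- vapply(cols, function(nm)
    st$depth[st_resolve(st, nm)] - st$depth[base], integer(1))
  sp_levels <- max(c(1L, vis_depth))
  col_label_h <- (max(nchar(cols)) + 1L) * cf$label_px
  sp_h <- (sp_levels + 1L) * cf$sp_level_h
  matrix_y0 <- sp_h + col_label_h

  col_x <- matrix_x0 + (seq_len(nc) - 0.5) * cf$cell_w

  # species-tree nodes above the columns: each visible column is a tip; walk
  # up from tips to the base, averaging child x per internal node
  sp_nodes <- new.env(parent = emptyenv())
  clade_color_of <- function(v) {
    for (nm in names(state$clade_colors)) {
      if (st_is_desc(st, v, st_resolve(st, nm))) return(state$clade_colors[[nm]])
    }
    NA_character_
  }
  place_sp <- function(v) {
    key <- st$name[v]
    if (!is.null(sp_nodes[[key]])) return(sp_nodes[[key]])
    j <- match(key, cols)
    if (!is.na(j)) {
      nd <- list(x = col_x[j], y = matrix_y0 - col_label_h,
                 depth = st$depth[v] - st$depth[base])
    } else {
      kid_x <- vapply(st$children[[v]], function(ch) place_sp(ch)$x, 0)
      nd <- list(x = mean(kid_x), y = (st$depth[v] - st$depth[base]) * cf$sp_level_h,
                 depth = st$depth[v] - st$depth[base])
    }
    sp_nodes[[key]] <- nd
    nd
  }
  vis_sp <- function(v) {
    # visible species nodes: base down to column tips
    key <- st$name[v]
    if (key %in% cols) return(key)
    c(key, unlist(lapply(st$children[[v]], vis_sp)))
  }
  sp_visible <- vis_sp(base)
  for (nm in sp_visible) place_sp(st_resolve(st, nm))
  # tips hang at a fixed level just above the labels; internals by depth
  sp_df <- do.call(rbind, lapply(sp_visible, function(nm) {
    v <- st_resolve(st, nm)
    nd <- sp_nodes[[nm]]
    is_tip <- nm %in% cols
    data.frame(id = nm, x = nd$x,
               y = if (is_tip) sp_h - cf$sp_level_h * 0.25
                   else nd$depth * cf$sp_level_h,
               parent = if (v == base) NA_character_ else st$name[st$parent[v]],
               tip = is_tip, color = clade_color_of(v),
               stringsAsFactors = FALSE)
  }))

  # --- rows ------------------------------------------------------------------
  row_fams <- vapply(rows, `[[`, "", "family_id")
  y <- matrix_y0
  row_y <- numeric(length(rows))
  for (i in seq_along(rows)) {
    if (i > 1L && row_fams[i] != row_fams[i - 1L]) y <- y + cf$family_gap
    row_y[i] <- y + 0.5 * cf$cell_h
    y <- y + cf$cell_h
  }
  total_h <- y + 20
  rows_df <- data.frame(
    family = row_fams,
    tip = vapply(rows, `[[`, "", "tip_id"),
    label = labels,
    taxon = vapply(rows, `[[`, "", "origin_taxon"),
    y = row_y, stringsAsFactors = FALSE)

  # --- gene trees ------------------------------------------------------------
  gene_nodes <- list(); gene_edges <- list()
  for (fid in fam_ids) {
    tr <- trees[[match(fid, fam_ids)]]
    tip_rows <- which(rows_df$family == fid)
    k <- 0L
    assign_y <- function(t, depth) {
      x <- gene_x0 + depth * cf$indent
      if (length(t$children) == 0L) {
        k <<- k + 1L
        yy <- rows_df$y[tip_rows[k]]
      } else {
        kid <- lapply(t$children, assign_y, depth = depth + 1L)
        yy <- mean(vapply(kid, `[[`, 0, "y"))
        nlv <- vapply(kid, `[[`, 0, "n")
        for (i in seq_along(kid)) {
          gene_edges[[length(gene_edges) + 1L]] <<- data.frame(
            family = fid, x1 = x, y1 = yy, x2 = kid[[i]]$x, y2 = kid[[i]]$y,
            width = branch_width(max(1, nlv[i]), cf$max_branch_width),
            stringsAsFactors = FALSE)
        }
      }
      n_extant <- sum(leaf_counts(t$node))
      gene_nodes[[length(gene_nodes) + 1L]] <<- data.frame(
        family = fid, id = t$node$id, x = x, y = yy,
        collapsed = t$collapsed, event = t$node$event,
        stringsAsFactors = FALSE)
      list(x = x, y = yy, n = n_extant)
    }
    assign_y(tr, 0L)
  }
  gene_nodes <- do.call(rbind, gene_nodes)
  gene_edges <- if (length(gene_edges)) do.call(rbind, gene_edges)
    else data.frame(family = character(0), x1 = numeric(0), y1 = numeric(0),
                    x2 = numeric(0), y2 = numeric(0), width = numeric(0))

  # --- cells -----------------------------------------------------------------
  cells <- list()
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    for (j in seq_len(nc)) {
      if (r$kind[j] == "OUTGROUP") next
      v <- if (r$kind[j] == "LOST") 0 else r$value[j]
      cells[[length(cells) + 1L]] <- data.frame(
        row = i, col = j, kind = r$kind[j], value = v,
        intensity = shade(v, matrix$vmax),
        display = if (r$kind[j] == "LOST") "0" else display_value(v),
        stringsAsFactors = FALSE)
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells)
    else data.frame(row = integer(0), col = integer(0), kind = character(0),
                    value = numeric(0), intensity = numeric(0),
                    display = character(0))

  structure(list(
    config = cf, columns = cols, col_x = col_x, matrix_x0 = matrix_x0,
    matrix_y0 = matrix_y0, label_w = label_w, sp_h = sp_h,
    width = matrix_x0 + nc * cf$cell_w + 12 * max(nchar(c(rows_df$taxon, "tax"))),
    height = total_h, sp_nodes = sp_df, rows = rows_df,
    gene_nodes = gene_nodes, gene_edges = gene_edges, cells = cells,
    clade_colors = state$clade_colors),
    class = "render_model")
}

# integers bare, otherwise one decimal (internal arithmetic stays exact)
display_value <- function(v) {
  if (v == round(v)) sprintf("%d", as.integer(round(v)))
  else sprintf("%.1f", v)
}

fmt2 <- function(x) sprintf("%.2f", x)

ramp_fill <- function(intensity, ramp_color) {
  m <- grDevices::colorRamp(c("#ffffff", ramp_color))(intensity)
  grDevices::rgb(round(m[, 1]), round(m[, 2]), round(m[, 3]),
                 maxColorValue = 255)
}

#' Emit a render model as a standalone SVG file
#'
#' LOST cells are drawn as gray-background zeros, OUTGROUP cells stay
#' blank; clade colors apply to species-tree branches and column labels.
#' Output is byte-identical across runs for a fixed state.
#'
#' @param model a `render_model` from [layout_view()].
#' @param path output file; `NULL` returns the SVG text.
#' @return The path (or the SVG string when `path` is NULL), invisibly.
#' @export
emit_svg <- function(model, path = NULL) {
  cf <- model$config
  out <- c(sprintf(
    paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
           'width="%s" height="%s" font-family="Helvetica,sans-serif">'),
    fmt2(model$width), fmt2(model$height)),
    '<rect width="100%" height="100%" fill="#ffffff"/>')

  # species tree (elbow connectors)
  sp <- model$sp_nodes
  for (i in seq_len(nrow(sp))) {
    if (is.na(sp$parent[i])) next
    p <- sp[sp$id == sp$parent[i], ]
    col <- if (!is.na(sp$color[i])) sp$color[i] else "#555555"
    out <- c(out, sprintf(
      '<path d="M %s %s V %s H %s" fill="none" stroke="%s" stroke-width="1.2"/>',
      fmt2(sp$x[i]), fmt2(sp$y[i]), fmt2(p$y[1]), fmt2(p$x[1]), col))
  }
  # column labels (vertical)
  for (j in seq_along(model$columns)) {
    nm <- model$columns[j]
    col <- "#000000"
    tip <- model$sp_nodes[model$sp_nodes$id == nm, ]
    if (nrow(tip) && !is.na(tip$color[1])) col <- tip$color[1]
    out <- c(out, sprintf(
      '<text x="%s" y="%s" transform="rotate(-90 %s %s)" font-size="10" fill="%s" text-anchor="start">%s</text>',
      fmt2(model$col_x[j] + 3), fmt2(model$matrix_y0 - 4),
      fmt2(model$col_x[j] + 3), fmt2(model$matrix_y0 - 4), col,
      xml_escape(nm)))
  }

  # gene trees
  ge <- model$gene_edges
  for (i in seq_len(nrow(ge))) {
    out <- c(out, sprintf(
      '<path d="M %s %s V %s H %s" fill="none" stroke="#333333" stroke-width="%s" stroke-linecap="round"/>',
      fmt2(ge$x1[i]), fmt2(ge$y1[i]), fmt2(ge$y2[i]), fmt2(ge$x2[i]),
      fmt2(ge$width[i])))
  }
  gn <- model$gene_nodes
  for (i in seq_len(nrow(gn))) {
    if (gn$event[i] == "duplication" && !gn$collapsed[i]) {
      out <- c(out, sprintf(
        '<rect x="%s" y="%s" width="6" height="6" fill="#c0392b"/>',
        fmt2(gn$x[i] - 3), fmt2(gn$y[i] - 3)))
    } else if (gn$collapsed[i]) {
      out <- c(out, sprintf(
        '<path d="M %s %s l 8 -4 l 0 8 z" fill="#2c3e50"/>',
        fmt2(gn$x[i]), fmt2(gn$y[i])))
    }
  }

  # row labels (left) and origin-taxon annotation (right)
  rows <- model$rows
  lab_x <- model$matrix_x0 - 6
  right_x <- model$matrix_x0 + length(model$columns) * cf$cell_w + 6
  for (i in seq_len(nrow(rows))) {
    ital <- if (startsWith(rows$label[i], "loss:")) ' font-style="italic"' else ""
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="10" text-anchor="end"%s>%s</text>',
      fmt2(lab_x), fmt2(rows$y[i] + 3), ital, xml_escape(rows$label[i])))
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="9" fill="#777777">%s</text>',
      fmt2(right_x), fmt2(rows$y[i] + 3), xml_escape(rows$taxon[i])))
  }

  # matrix cells
  cells <- model$cells
  fills <- if (nrow(cells)) ramp_fill(cells$intensity, cf$ramp_color)
    else character(0)
  for (i in seq_len(nrow(cells))) {
    x <- model$matrix_x0 + (cells$col[i] - 1) * cf$cell_w
    yy <- rows$y[cells$row[i]] - 0.5 * cf$cell_h
    fill <- if (cells$kind[i] == "LOST") "#d9d9d9" else fills[i]
    tcol <- if (cells$kind[i] != "LOST" && cells$intensity[i] > 0.55)
      "#ffffff" else "#000000"
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#eeeeee"/>',
      fmt2(x), fmt2(yy), fmt2(cf$cell_w), fmt2(cf$cell_h), fill))
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="10" text-anchor="middle" fill="%s">%s</text>',
      fmt2(x + 0.5 * cf$cell_w), fmt2(yy + 0.5 * cf$cell_h + 3.5), tcol,
      cells$display[i]))
  }
  out <- c(out, "</svg>")
  svg <- paste(out, collapse = "\n")
  if (is.null(path)) return(invisible(svg))
  writeLines(svg, path, useBytes = TRUE)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Emit a self-contained HTML page for a view state
#'
#' One file, no network assets: the static SVG plus the serialized view
#' (families, collapse sets, columns, profile values) embedded as JSON for
#' downstream tooling, and a minimal inline script wiring cell tooltips.
#'
#' @param state a `view_state`.
#' @param path output file path.
#' @param matrix its `profile_matrix` (defaults to computing it).
#' @param config geometry options from `render_config()`.
#' @return `path`, invisibly.
#' @export
emit_html <- function(state, path, matrix = profile_matrix(state),
                      config = render_config()) {
  model <- layout_view(state, matrix, config)
  svg <- emit_svg(model, path = NULL)
  payload <- list(
    families = lapply(state$families, function(f)
      jsonlite::fromJSON(family_to_json(f), simplifyVector = FALSE)),
    collapsed = state$collapsed,
    collapsed_taxa = state$collapsed_taxa,
    columns = matrix$columns,
    rows = lapply(matrix$rows, function(r)
      list(family = r$family_id, tip = r$tip_id, label = r$label,
           taxon = r$origin_taxon, kind = r$kind,
           value = ifelse(is.na(r$value), NA, r$value))),
    vmax = matrix$vmax)
  json <- as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                        digits = NA, null = "null",
                                        na = "null"))
  html <- c(
    "<!DOCTYPE html>",
    '<html lang="en"><head><meta charset="utf-8"/>',
    "<title>gene family view</title>",
    "<style>body{margin:12px;font-family:Helvetica,sans-serif}</style>",
    "</head><body>",
    svg,
    sprintf('<script type="application/json" id="view-state">%s</script>',
            json),
    "<script>",
    "// static page: the embedded view-state JSON carries the full matrix",
    "// (families, collapse sets, per-row profile values) for downstream use.",
    "var state=JSON.parse(document.getElementById('view-state').textContent);",
    "document.querySelectorAll('svg rect').forEach(function(r){r.addEventListener('mouseover',function(){r.setAttribute('stroke','#333333');});r.addEventListener('mouseout',function(){r.setAttribute('stroke','#eeeeee');});});",
    "</script>",
    "</body></html>")
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}
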