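# Spatial correlation pathway networks: Spearman rank correlation of ion
# images over a masked region, edges between annotated metabolites sharing
# a pathway, nodes retained only with at least one significant correlation,
# |rho| exported as the layout weight.

#' Spatial Spearman correlation of two ion images
#'
#' Spearman's rank correlation (midrank ties) of the two images over the
#' masked pixels, with the usual t-approximation for the p-value.
#'
#' @param img_i,img_j Numeric vectors of pixel intensities on the same grid
#'   (e.g. data cube columns).
#' @param mask_idx Integer indices of the masked pixels (>= 3).
#' @return List with `rho` and two-sided `p`; a constant image yields
#'   `rho = NA` with a warning.
#' @export
spatial_spearman <- function(img_i, img_j, mask_idx = seq_along(img_i)) {
  if (length(img_i) != length(img_j)) stop("images must share the grid")
  x <- img_i[mask_idx]
  y <- img_j[mask_idx]
  n <- length(x)
  if (n < 3L) stop("need at least 3 masked pixels")
  if (max(x) == min(x) || max(y) == min(y)) {
    warning("constant image within mask; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Build the spatial correlation pathway network
#'
#' Nodes are annotated peaks (one node per peak, best annotation). Candidate
#' edges connect pairs whose metabolites share at least one pathway; every
#' candidate edge is kept and attributed with the spatial Spearman rho and p
#' over the masked pixels. Nodes lacking any correlation with `p <= alpha`
#' (and `|rho| >= rho_floor`) are dropped, together with their edges. Node
#' attributes carry the metabolite name, log2 fold change and a label flag
#' for `|log2FC| >= label_fc`; edge attributes carry rho, p, `|rho|` (the
#' layout weight) and the shared pathways.
#'
#' @param annos Annotation data frame (deduplicated internally per peak).
#' @param stat_table Stat table with `peak_mz` and `log2fc`.
#' @param cube `msi_datacube` providing the ion images.
#' @param mask [roi_mask()]; correlations are computed within `roi_labels`.
#' @param alpha Significance level for node retention (default 0.05,
#'   unadjusted).
#' @param roi_labels Mask labels of the correlation region (default cortical
#'   bone).
#' @param rho_floor Optional minimal |rho| for a correlation to count as
#'   significant (default 0).
#' @param label_fc Absolute log2FC threshold for the node label flag.
#' @return An `igraph` graph; may be empty.
#' @export
build_network <- function(annos, stat_table, cube, mask, alpha = 0.05,
                          roi_labels = c("mineralized_bone", "osteoid"),
                          rho_floor = 0, label_fc = 1) {
  best <- best_annotation(annos)
  if (nrow(best) == 0L) stop("empty annotation set")
  best <- best[order(best$peak_mz), , drop = FALSE]
  peak_idx <- match(best$peak_mz, cube$peak_mz)
  if (any(is.na(peak_idx))) stop("annotated peaks missing from the cube")
  lab <- mask_labels(mask, cube$coords)
  mask_idx <- which(lab %in% roi_labels)
  if (length(mask_idx) < 3L) stop("mask selects fewer than 3 pixels")
  fc <- stat_table$log2fc[match(best$peak_mz, stat_table$peak_mz)]

  n <- nrow(best)
  pw <- strsplit(best$pathways, ";", fixed = TRUE)
  edges <- list()
  for (i in seq_len(n - 1L)) {
    if (!length(pw[[i]]) || !nzchar(pw[[i]][1])) next
    for (j in seq((i + 1L), n)) {
      shared <- intersect(pw[[i]], pw[[j]])
      shared <- shared[nzchar(shared)]
      if (!length(shared)) next
      sp <- spatial_spearman(cube$intensity[, peak_idx[i]],
                             cube$intensity[, peak_idx[j]], mask_idx)
      edges[[length(edges) + 1L]] <- data.frame(
        from = i, to = j, rho = sp$rho, p = sp$p,
        shared_pathways = paste(sort(shared), collapse = ";"))
    }
  }
  edges <- do.call(rbind, edges)

  nodes <- data.frame(
    name = sprintf("peak_%.4f", best$peak_mz),
    metabolite = best$name, metabolite_id = best$id,
    peak_mz = best$peak_mz, adduct = best$adduct,
    log2fc = ifelse(is.na(fc), 0, fc),
    labelled = !is.na(fc) & abs(fc) >= label_fc,
    pathways = best$pathways, stringsAsFactors = FALSE)

  if (is.null(edges)) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  sig <- !is.na(edges$p) & edges$p <= alpha & abs(edges$rho) >= rho_floor
  keep_node <- sort(unique(c(edges$from[sig], edges$to[sig])))
  if (!length(keep_node)) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  edges <- edges[edges$from %in% keep_node & edges$to %in% keep_node, ,
                 drop = FALSE]
  el <- data.frame(from = nodes$name[edges$from], to = nodes$name[edges$to],
                   rho = edges$rho, p = edges$p,
                   abs_rho = abs(edges$rho),
                   shared_pathways = edges$shared_pathways)
  g <- igraph::graph_from_data_frame(
    el, directed = FALSE,
    vertices = nodes[keep_node, , drop = FALSE])
  g
}

.fmt10 <- function(x) sprintf("%.10g", x)

#' Export a correlation network as GraphML
#'
#' Hand-rendered GraphML with typed node attributes (metabolite name, m/z,
#' adduct, log2FC, label flag, pathways) and edge attributes (rho, p,
#' abs_rho as layout weight, shared pathways). Numeric attributes are
#' written as decimal strings with 10 significant digits; the file loads in
#' igraph and other standard graph tools.
#'
#' @param net An `igraph` network from [build_network()].
#' @param path Output `.graphml` path.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(net, path) {
  stopifnot(inherits(net, "igraph"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  node_attrs <- list(
    c("metabolite", "string"), c("metabolite_id", "string"),
    c("peak_mz", "double"), c("adduct", "string"),
    c("log2fc", "double"), c("labelled", "boolean"),
    c("pathways", "string"))
  edge_attrs <- list(
    c("rho", "double"), c("p", "double"), c("abs_rho", "double"),
    c("shared_pathways", "string"))

  keys <- c(
    vapply(node_attrs, function(a) sprintf(
      '  <key id="v_%s" for="node" attr.name="%s" attr.type="%s"/>',
      a[1], a[1], a[2]), character(1)),
    vapply(edge_attrs, function(a) sprintf(
      '  <key id="e_%s" for="edge" attr.name="%s" attr.type="%s"/>',
      a[1], a[1], a[2]), character(1)))

  nv <- igraph::vcount(net)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns"',
    '         xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance"',
    '         xsi:schemaLocation="http://graphml.graphdrawing.org/xmlns http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd">',
    keys,
    '  <graph id="G" edgedefault="undirected">')
  if (nv > 0) {
    vnames <- igraph::V(net)$name
    for (i in seq_len(nv)) {
      data <- vapply(node_attrs, function(a) {
        val <- igraph::vertex_attr(net, a[1])[i]
        val <- if (a[2] == "double") .fmt10(val)
               else if (a[2] == "boolean") tolower(as.character(val))
               else esc(as.character(val))
        sprintf('      <data key="v_%s">%s</data>', a[1], val)
      }, character(1))
      lines <- c(lines,
                 sprintf('    <node id="%s">', esc(vnames[i])), data,
                 '    </node>')
    }
    if (igraph::ecount(net) > 0) {
      el <- igraph::as_edgelist(net, names = TRUE)
      for (j in seq_len(nrow(el))) {
        data <- vapply(edge_attrs, function(a) {
          val <- igraph::edge_attr(net, a[1])[j]
          val <- if (a[2] == "double") .fmt10(val) else esc(as.character(val))
          sprintf('      <data key="e_%s">%s</data>', a[1], val)
        }, character(1))
        lines <- c(lines,
                   sprintf('    <edge source="%s" target="%s">',
                           esc(el[j, 1]), esc(el[j, 2])),
                   data, '    </edge>')
      }
    }
  }
  lines <- c(lines, '  </graph>', '</graphml>')
  con <- file(path, "wb")
  writeLines(lines, con, useBytes = TRUE)
  close(con)
  invisible(path)
}

#' Export the network's node and edge tables as TSV
#'
#' @param net An `igraph` network.
#' @param node_path,edge_path Output paths.
#' @return Invisibly, the two paths.
#' @export
export_network_tables <- function(net, node_path, edge_path) {
  nodes <- igraph::as_data_frame(net, what = "vertices")
  edges <- igraph::as_data_frame(net, what = "edges")
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(node_path, edge_path))
}
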