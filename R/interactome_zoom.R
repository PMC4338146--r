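# Confidence-weighted interaction graphs and query-centric "zooming level"
# subgraph extraction (L1/L2/L3) with connected-component reporting.

#' Build an interaction graph from an edge data frame
#'
#' Edges below or at the confidence threshold are discarded (the comparison
#' is strict, following the high-confidence convention `> 0.7`); duplicate
#' pairs collapse to the maximum confidence; self-loops are dropped with a
#' warning. Gene ids are matched case-insensitively; the first-seen spelling
#' is kept for display.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `confidence`.
#' @param threshold Confidence threshold in `[0, 1]`; default 0.7.
#' @param rescale If `TRUE`, integer-style scores on a 0-1000 scale are
#'   divided by 1000 before validation.
#' @return An undirected `igraph` graph with edge attribute `confidence`.
#' @export
make_interaction_graph <- function(edges, threshold = 0.7, rescale = FALSE) {
  stopifnot(is.data.frame(edges))
  if (!all(c("gene_a", "gene_b", "confidence") %in% names(edges)))
    stop("`edges` needs columns gene_a, gene_b, confidence")
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("`threshold` must be in [0, 1]")
  conf <- as.numeric(edges$confidence)
  if (anyNA(conf)) stop("non-numeric confidence value(s)")
  if (rescale) conf <- conf / 1000
  if (any(conf < 0 | conf > 1))
    stop("confidence values outside [0, 1]")
  a <- as.character(edges$gene_a); b <- as.character(edges$gene_b)
  spell <- c(a, b); spell <- spell[!duplicated(canonical_gene(spell))]
  names(spell) <- canonical_gene(spell)
  ka <- canonical_gene(a); kb <- canonical_gene(b)
  loop <- ka == kb
  if (any(loop)) {
    warning(sum(loop), " self-loop(s) dropped")
    ka <- ka[!loop]; kb <- kb[!loop]; conf <- conf[!loop]
  }
  lo <- pmin(ka, kb); hi <- pmax(ka, kb)
  key <- paste(lo, hi, sep = "\r")
  conf <- vapply(split(conf, key), max, numeric(1))
  if (!length(conf))
    return(igraph::make_empty_graph(directed = FALSE))
  pairs <- do.call(rbind, strsplit(names(conf), "\r", fixed = TRUE))
  keep <- conf > threshold
  df <- data.frame(from = unname(spell[pairs[keep, 1]]),
                   to = unname(spell[pairs[keep, 2]]),
                   confidence = unname(conf[keep]),
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Load a confidence-weighted interaction edge list
#'
#' Reads a TSV of `gene_a<TAB>gene_b<TAB>confidence` rows (a header line is
#' detected and skipped) and builds the thresholded graph via
#' [make_interaction_graph()].
#'
#' @inheritParams make_interaction_graph
#' @param path Path to the edge-list TSV.
#' @return An undirected `igraph` graph.
#' @export
load_edges <- function(path, threshold = 0.7, rescale = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  if (any(nfld < 3L))
    stop(sprintf("malformed edge row at line %d: expected 3 tab-separated fields",
                 which(nfld < 3L)[1L]))
  first_conf <- suppressWarnings(as.numeric(parts[[1L]][3L]))
  if (length(parts) && is.na(first_conf)) parts <- parts[-1L]  # header
  if (!length(parts)) stop("empty edge list")
  conf <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  if (anyNA(conf))
    stop(sprintf("malformed confidence at line %d",
                 which(is.na(conf))[1L] + (length(lines) - length(parts))))
  edges <- data.frame(gene_a = vapply(parts, `[[`, character(1), 1L),
                      gene_b = vapply(parts, `[[`, character(1), 2L),
                      confidence = conf, stringsAsFactors = FALSE)
  make_interaction_graph(edges, threshold = threshold, rescale = rescale)
}

#' Write an edge list TSV
#' @param edges Data frame with columns `gene_a`, `gene_b`, `confidence`.
#' @param path Output file path.
#' @param header Write a header line (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path, header = TRUE) {
  utils::write.table(edges[, c("gene_a", "gene_b", "confidence")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = header)
  invisible(path)
}

#' Extract a zooming-level subgraph around query genes
#'
#' The three query-centric views of an interaction graph:
#' \describe{
#'   \item{level 1}{query genes plus every gene with at least one interaction
#'     with a query gene;}
#'   \item{level 2}{query genes plus genes interacting with at least two
#'     distinct query genes;}
#'   \item{level 3}{the query genes only ("query network": direct
#'     interactions between query genes).}
#' }
#' The returned edge set is the subgraph induced by the selected nodes, so
#' the node sets are nested: L3 is a subset of L2 is a subset of L1.
#' `deg_to_query` counts distinct query neighbors, not multi-edges.
#'
#' @param graph An `igraph` interaction graph.
#' @param query A `gene_list` or character vector of query genes (matched
#'   case-insensitively; genes absent from the graph are ignored for
#'   neighborhood counting but reported in `missing`).
#' @param level Zooming level: 1, 2 or 3.
#' @return An object of class `zoom_result`: list with `level`,
#'   `query_genes`, `graph` (induced `igraph` subgraph), `nodes`,
#'   `components` (node sets sorted by decreasing size, ties broken by
#'   smallest member id) and `missing` (query genes absent from the graph).
#' @export
zoom <- function(graph, query, level = c(1L, 2L, 3L)) {
  stopifnot(inherits(graph, "igraph"))
  level <- as.integer(level)
  level <- match.arg(as.character(level), c("1", "2", "3"))
  level <- as.integer(level)
  if (inherits(query, "gene_list")) query <- query$members
  query <- as.character(query)
  if (!length(query)) stop("empty query gene set")
  vnames <- igraph::V(graph)$name
  vkey <- canonical_gene(vnames)
  qkey <- unique(canonical_gene(query))
  q_in <- vnames[vkey %in% qkey]
  missing <- query[!canonical_gene(query) %in% vkey]
  if (level == 3L) {
    nodes <- q_in
  } else {
    # distinct-query-neighbor count per non-query vertex
    nonq <- setdiff(vnames, q_in)
    if (length(q_in)) {
      nb <- igraph::adjacent_vertices(graph, v = q_in)
      touch <- table(unlist(lapply(nb, function(v) unique(v$name)),
                            use.names = FALSE))
      touch <- touch[setdiff(names(touch), q_in)]
    } else touch <- integer(0)
    thr <- if (level == 1L) 1L else 2L
    nodes <- c(q_in, names(touch)[touch >= thr])
  }
  sub <- igraph::induced_subgraph(graph, vids = nodes)
  structure(list(level = level, query_genes = q_in, graph = sub,
                 nodes = igraph::V(sub)$name,
                 components = component_sets(sub),
                 missing = missing),
            class = "zoom_result")
}

# components of an igraph, sorted by decreasing size then smallest member id
component_sets <- function(g) {
  if (igraph::vcount(g) == 0L) return(list())
  comp <- igraph::components(g)
  sets <- split(igraph::V(g)$name, comp$membership)
  sets <- lapply(sets, function(s) s[order(s)])
  ord <- order(-lengths(sets),
               vapply(sets, `[[`, character(1), 1L))
  unname(sets[ord])
}

#' Connected components of a zoom result
#'
#' @param result A `zoom_result`.
#' @return List of components, each a list with `members` (sorted gene ids)
#'   and `size`, ordered by decreasing size with ties broken by the smallest
#'   member id.
#' @export
zoom_components <- function(result) {
  stopifnot(inherits(result, "zoom_result"))
  lapply(component_sets(result$graph),
         function(s) list(members = s, size = length(s)))
}

#' @export
print.zoom_result <- function(x, ...) {
  cat(sprintf("zoom_result level %d: %d nodes, %d edges, %d component(s)\n",
              x$level, length(x$nodes), igraph::ecount(x$graph),
              length(x$components)))
  sz <- lengths(x$components)
  if (length(sz)) cat("  component sizes:", paste(sz, collapse = ", "), "\n")
  invisible(x)
}

#' Per-gene level-2 neighborhood of a seed gene
#'
#' Convenience view of the interactions around a single gene within a list:
#' the query set is the seed gene plus its direct interaction partners that
#' belong to `within` (its level-3 partners in the list), and the chosen
#' zooming level is then applied to that query. This is one interpretation
#' of a per-gene neighborhood display, provided as sugar over [zoom()].
#'
#' @param graph An `igraph` interaction graph.
#' @param seed_gene A single gene id.
#' @param within A `gene_list` (or character vector) restricting the seed's
#'   partners.
#' @param level Zooming level applied to the derived query (default 2).
#' @return A `zoom_result`.
#' @export
seed_gene_zoom <- function(graph, seed_gene, within, level = 2L) {
  stopifnot(length(seed_gene) == 1L)
  if (inherits(within, "gene_list")) within <- within$members
  vnames <- igraph::V(graph)$name
  seed <- vnames[canonical_gene(vnames) == canonical_gene(seed_gene)]
  if (!length(seed)) stop("seed gene not in graph: ", seed_gene)
  partners <- igraph::neighbors(graph, seed)$name
  partners <- partners[canonical_gene(partners) %in% canonical_gene(within)]
  zoom(graph, c(seed, partners), level = level)
}

#' Export subgraphs and component summaries
#'
#' `write_sif()` writes the simple interaction format (`a pp b` lines, one
#' line per isolated node); `write_zoom_graphml()` writes GraphML;
#' `write_components_json()` writes the component membership/size summary.
#'
#' @param x A `zoom_result` or `igraph` graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(x, path) {
  g <- if (inherits(x, "zoom_result")) x$graph else x
  el <- igraph::as_edgelist(g)
  lines <- if (nrow(el)) sprintf("%s\tpp\t%s", el[, 1], el[, 2]) else character()
  iso <- igraph::V(g)$name[igraph::degree(g) == 0L]
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_zoom_graphml <- function(x, path) {
  g <- if (inherits(x, "zoom_result")) x$graph else x
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_sif
#' @export
write_components_json <- function(x, path) {
  stopifnot(inherits(x, "zoom_result"))
  doc <- list(level = x$level,
              n_nodes = length(x$nodes),
              n_edges = igraph::ecount(x$graph),
              components = zoom_components(x))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
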