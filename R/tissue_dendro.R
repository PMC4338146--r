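# Tissue dendrogram: Spearman rank correlation of ordinal expression
# profiles, correlation -> distance, neighbor-joining tree, Newick export.

#' Pairwise-complete Spearman correlation between tissues
#'
#' Computes the tissue-by-tissue Spearman rank correlation of an ordinally
#' encoded annotation grid (see [encode_ordinal()]). For each tissue pair,
#' only genes unmasked (analyzed) in both tissues enter; ranks use average
#' tie handling, which the heavily tied ordinal data requires. Because the
#' statistic is rank-based it is invariant under any strictly monotone
#' recoding of the ordinal values.
#'
#' @param encoded Numeric genes x tissues matrix with `NA` for masked cells.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(encoded) {
  if (!is.matrix(encoded) || !is.numeric(encoded))
    stop("`encoded` must be a numeric matrix")
  p <- ncol(encoded)
  if (p < 2L) stop("need at least 2 tissues")
  labs <- colnames(encoded)
  if (is.null(labs)) labs <- paste0("V", seq_len(p))
  rho <- diag(1, p)
  dimnames(rho) <- list(labs, labs)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      ok <- !is.na(encoded[, i]) & !is.na(encoded[, j])
      if (sum(ok) < 3L)
        stop(sprintf(
          "tissues '%s' and '%s' share fewer than 3 analyzed genes",
          labs[i], labs[j]))
      ri <- rank(encoded[ok, i])  # average ranks on ties
      rj <- rank(encoded[ok, j])
      if (stats::sd(ri) == 0 || stats::sd(rj) == 0)
        stop(sprintf(
          "constant expression profile for tissue '%s' over the genes shared with '%s'; Spearman correlation undefined",
          if (stats::sd(ri) == 0) labs[i] else labs[j],
          if (stats::sd(ri) == 0) labs[j] else labs[i]))
      rho[i, j] <- rho[j, i] <- stats::cor(ri, rj)
    }
  }
  rho
}

#' Correlation to distance
#'
#' Elementwise `d = 1 - rho`: identical profiles are at distance 0, perfectly
#' reversed ones at 2. This is the standard correlation dissimilarity; the
#' transform preserves the ranking of similarities.
#'
#' @param corr Symmetric correlation matrix in `[-1, 1]`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
to_distance <- function(corr) {
  if (!is.matrix(corr) || !isSymmetric(unname(corr), tol = 1e-12))
    stop("`corr` must be a symmetric matrix")
  if (any(corr < -1 - 1e-9 | corr > 1 + 1e-9))
    stop("correlations outside [-1, 1]")
  d <- 1 - corr
  diag(d) <- 0
  d
}

#' Write a distance matrix as square TSV
#' @param d Square labelled distance matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distances <- function(d, path) {
  df <- data.frame(tissue = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_distance <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance input must be a square matrix")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("negative distances are not allowed")
  if (any(abs(diag(d)) > 1e-12)) stop("distance diagonal must be zero")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("L", seq_len(nrow(d)))
  d
}

# Newick-quote a label if needed (tissue ids are normally plain)
nwk_label <- function(x) {
  if (grepl("[] (){}:;,'[]", x)) paste0("'", gsub("'", "''", x), "'") else x
}

#' Build an unrooted tissue tree by neighbor joining
#'
#' Canonical neighbor joining on a distance matrix, with two determinism
#' rules: ties on the Q criterion are broken by the lowest (row, column)
#' index pair, and negative branch-length estimates are clamped to zero.
#' On an additive distance matrix the generating topology and branch lengths
#' are recovered exactly (NJ consistency), which is also how the engine is
#' validated.
#'
#' @param d Square symmetric distance matrix (or `dist`) with >= 3 labels;
#'   >= 4 labels for a non-trivial topology.
#' @return An unrooted `ape::phylo` tree with tip labels from the matrix.
#' @export
build_tree <- function(d) {
  d <- validate_distance(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labs <- rownames(d)
  # each active node carries a growing newick fragment
  frag <- vapply(labs, nwk_label, character(1))
  act <- d
  while (nrow(act) > 3L) {
    m <- nrow(act)
    r <- rowSums(act)
    q <- (m - 2) * act - outer(r, r, `+`)
    diag(q) <- Inf
    # lowest (row, col) pair among minima, column-major scan of upper pairs
    best <- c(NA_integer_, NA_integer_)
    qmin <- Inf
    for (jj in 2:m) for (ii in 1:(jj - 1L)) {
      if (q[ii, jj] < qmin - 1e-12) { qmin <- q[ii, jj]; best <- c(ii, jj) }
    }
    i <- best[1L]; j <- best[2L]
    li <- act[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- act[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], li, frag[j], lj)
    dk <- (act[i, ] + act[j, ] - act[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], dk[keep]),
                 c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
  }
  if (nrow(act) == 3L) {
    l1 <- max((act[1, 2] + act[1, 3] - act[2, 3]) / 2, 0)
    l2 <- max((act[1, 2] + act[2, 3] - act[1, 3]) / 2, 0)
    l3 <- max((act[1, 3] + act[2, 3] - act[1, 2]) / 2, 0)
    nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                   frag[1], l1, frag[2], l2, frag[3], l3)
  }
  tree <- ape::read.tree(text = nwk)
  tree
}

#' Newick serialization
#'
#' Emits a Newick string with branch lengths; `file` writes it instead.
#' Emit-then-parse round trips to an isomorphic tree.
#'
#' @param tree An `ape::phylo` tree.
#' @param file Optional output path.
#' @return The Newick string (invisibly when `file` is given).
#' @export
to_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

#' Cut a tree into k groups by longest-branch removal
#'
#' A simple partitioning utility: removes the `k - 1` longest edges and
#' returns the leaf sets of the resulting components. This is a labelled
#' approximation of dendrogram partitioning, not a reimplementation of any
#' published clustering method.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param k Number of groups (>= 1).
#' @return List of `k` character vectors of tip labels.
#' @export
cut_tree_groups <- function(tree, k) {
  stopifnot(inherits(tree, "phylo"), k >= 1L)
  if (k == 1L) return(list(tree$tip.label))
  ne <- nrow(tree$edge)
  if (k - 1L > ne) stop("k too large for this tree")
  drop <- order(tree$edge.length, decreasing = TRUE)[seq_len(k - 1L)]
  nodes <- as.character(sort(unique(as.vector(tree$edge))))
  kept <- tree$edge[-drop, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(kept[, 1]), to = as.character(kept[, 2])),
    directed = FALSE, vertices = nodes)
  comp <- igraph::components(g)
  tips <- as.character(seq_along(tree$tip.label))
  groups <- split(tips, comp$membership[tips])
  out <- lapply(groups, function(ix) tree$tip.label[as.integer(ix)])
  out[order(-vapply(out, length, integer(1)))]
}

#' Full pipeline: annotation matrix to tissue tree
#'
#' Convenience wrapper chaining [encode_ordinal()], [spearman_matrix()],
#' [to_distance()] and [build_tree()].
#'
#' @param x An `annotation_matrix`.
#' @return List with elements `correlation`, `distance`, `tree`.
#' @export
tissue_dendrogram <- function(x) {
  enc <- encode_ordinal(x)
  rho <- spearman_matrix(enc)
  d <- to_distance(rho)
  list(correlation = rho, distance = d, tree = build_tree(d))
}
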