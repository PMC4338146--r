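# Fixture builders and independent oracles used across the suite.

STATES5 <- c("na", "negative", "weak", "medium", "strong")

# iid random annotation matrix; per-state probabilities shared by tissues
random_ann <- function(n_genes, tissues,
                       probs = c(na = 0.03, negative = 0.45, weak = 0.3,
                                 medium = 0.15, strong = 0.07)) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  states <- matrix(sample(STATES5, n_genes * length(tissues), replace = TRUE,
                          prob = probs),
                   n_genes, length(tissues),
                   dimnames = list(genes, tissues))
  annotation_matrix(states)
}

# ---- sieve oracle ----------------------------------------------------------
# neutral query representation, rendered to text for the implementation and
# evaluated gene-by-gene for the oracle
random_query_spec <- function(tissues, n_leaves = 3L, p_na = 0.15) {
  leaf <- function() {
    states <- if (runif(1) < 0.25) c("weak", "medium", "strong") else {
      pool <- if (runif(1) < p_na) STATES5 else STATES5[-1]
      sample(pool, sample.int(min(3L, length(pool)), 1L))
    }
    list(kind = "leaf", tissue = sample(tissues, 1L), states = unique(states))
  }
  build <- function(k) {
    if (k == 1L) return(leaf())
    split <- sample.int(k - 1L, 1L)
    list(kind = "node", op = sample(c("AND", "OR"), 1L),
         kids = list(build(split), build(k - split)))
  }
  build(n_leaves)
}

render_query_spec <- function(q) {
  if (q$kind == "leaf")
    return(sprintf("%s in {%s}", q$tissue, paste(q$states, collapse = ",")))
  sprintf("(%s %s %s)", render_query_spec(q$kids[[1]]), q$op,
          render_query_spec(q$kids[[2]]))
}

# truth-table evaluation, one gene at a time
oracle_eval_spec <- function(states_row, q) {
  if (q$kind == "leaf") return(states_row[[q$tissue]] %in% q$states)
  a <- oracle_eval_spec(states_row, q$kids[[1]])
  b <- oracle_eval_spec(states_row, q$kids[[2]])
  if (q$op == "AND") a && b else a || b
}

oracle_sieve <- function(ann, q) {
  genes <- ann_genes(ann)
  keep <- vapply(genes, function(g)
    oracle_eval_spec(as.list(ann$states[g, ]), q), logical(1))
  genes[keep]
}

# ---- zoom oracle -----------------------------------------------------------
# exhaustive per-node distinct-query-neighbor counting on a raw edge list
oracle_zoom_nodes <- function(edges, query, level) {
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  q <- intersect(query, nodes)
  if (level == 3L) return(sort(q))
  deg_to_q <- vapply(setdiff(nodes, q), function(v) {
    nb <- unique(c(edges$gene_b[edges$gene_a == v],
                   edges$gene_a[edges$gene_b == v]))
    length(intersect(nb, q))
  }, integer(1))
  thr <- if (level == 1L) 1L else 2L
  sort(c(q, names(deg_to_q)[deg_to_q >= thr]))
}

# union-find connected components over an edge list restricted to `nodes`
oracle_components <- function(edges, nodes) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    if (a %in% nodes && b %in% nodes) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(nodes, find, character(1))
  sets <- split(nodes, roots)
  sets <- lapply(sets, sort)
  unname(sets[order(-lengths(sets), vapply(sets, `[[`, character(1), 1L))])
}

# ---- tree oracles ----------------------------------------------------------
# enumerate all unrooted binary topologies on n leaves (edge lists; leaves
# 1..n, internal nodes n+1, ...)
enumerate_topologies <- function(n) {
  base <- list(list(edges = rbind(c(1L, n + 1L), c(2L, n + 1L), c(3L, n + 1L)),
                    next_node = n + 2L))
  for (leaf in seq_len(n)[-(1:3)]) {
    out <- list()
    for (t in base) {
      for (e in seq_len(nrow(t$edges))) {
        w <- t$next_node
        ed <- t$edges[-e, , drop = FALSE]
        ed <- rbind(ed, c(t$edges[e, 1L], w), c(w, t$edges[e, 2L]),
                    c(leaf, w))
        out[[length(out) + 1L]] <- list(edges = ed, next_node = w + 1L)
      }
    }
    base <- out
  }
  lapply(base, `[[`, "edges")
}

# OLS minimum-evolution fit: branch lengths by least squares on the
# path-incidence matrix; returns total tree length
ols_tree_length <- function(edges, d) {
  n <- nrow(d)
  pairs <- t(utils::combn(n, 2L))
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                   directed = FALSE)
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (p in seq_len(nrow(pairs))) {
    path <- igraph::shortest_paths(g, as.character(pairs[p, 1]),
                                   as.character(pairs[p, 2]))$vpath[[1]]
    vn <- igraph::as_ids(path)
    for (s in seq_len(length(vn) - 1L)) {
      hit <- which((edges[, 1] == vn[s] & edges[, 2] == vn[s + 1]) |
                   (edges[, 2] == vn[s] & edges[, 1] == vn[s + 1]))
      A[p, hit] <- 1
    }
  }
  y <- d[pairs]
  fit <- stats::lm.fit(A, y)
  sum(fit$coefficients)
}

# edge-list topology -> ape phylo (unit branch lengths), labels = taxa names
topology_to_phylo <- function(edges, labels) {
  n <- length(labels)
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                   directed = FALSE)
  build <- function(node, parent) {
    nb <- setdiff(igraph::as_ids(igraph::neighbors(g, node)), parent)
    if (!length(nb)) return(labels[as.integer(node)])
    paste0("(", paste(vapply(nb, function(ch) paste0(build(ch, node), ":1"),
                             character(1)), collapse = ","), ")")
  }
  root <- as.character(n + 1L)
  ape::read.tree(text = paste0(build(root, NULL), ";"))
}

# random unrooted tree with positive branch lengths and its additive matrix
random_additive <- function(n_taxa, lengths = NULL) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   tip.label = paste0("X", seq_len(n_taxa)))
  tr$edge.length <- if (is.null(lengths))
    stats::runif(nrow(tr$edge), 0.5, 3) else lengths
  list(tree = tr, d = stats::cophenetic(tr))
}

# unrooted monophyly: some edge separates `tips` from the rest
is_block_monophyletic <- function(tree, tips) {
  out <- setdiff(tree$tip.label, tips)[1L]
  rt <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  ape::is.monophyletic(rt, tips)
}

# components via igraph, independent of the package's own sorter
component_sets_for_test <- function(g) {
  comp <- igraph::components(g)
  unname(split(igraph::V(g)$name, comp$membership))
}
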