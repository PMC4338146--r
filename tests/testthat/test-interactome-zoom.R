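edge_df <- function(a, b, conf) {
  data.frame(gene_a = a, gene_b = b, confidence = conf,
             stringsAsFactors = FALSE)
}

test_that("edge loading: strict threshold, dedup to max, validation", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tconfidence",
               "A\tB\t0.70",          # exactly at threshold: excluded
               "A\tC\t0.8", "C\tA\t0.9",  # duplicate unordered pair
               "B\tC\t0.95"), tmp)
  g <- load_edges(tmp, threshold = 0.7)
  el <- igraph::as_edgelist(g)
  key <- apply(el, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(key, c("A-C", "B-C"))
  expect_equal(igraph::E(g)$confidence[key == "A-C"], 0.9)

  writeLines(c("A\tB"), tmp)
  expect_error(load_edges(tmp), "malformed")
  writeLines(c("A\tB\t1.5"), tmp)
  expect_error(load_edges(tmp), "outside \\[0, 1\\]")
  # 0-1000 STRING-style integer scores via rescale
  writeLines(c("A\tB\t850", "A\tC\t400"), tmp)
  g <- load_edges(tmp, threshold = 0.7, rescale = TRUE)
  expect_equal(igraph::ecount(g), 1L)
})

test_that("retained edges equal a line-by-line filter on random input", {
  set.seed(41)
  genes <- sprintf("n%02d", 1:20)
  a <- sample(genes, 100, replace = TRUE)
  b <- sample(genes, 100, replace = TRUE)
  conf <- round(runif(100), 3)
  keep <- a != b & conf > 0.7
  g <- suppressWarnings(
    make_interaction_graph(edge_df(a, b, conf), threshold = 0.7))
  got <- apply(igraph::as_edgelist(g), 1,
               function(r) paste(sort(r), collapse = "-"))
  want <- unique(mapply(function(x, y) paste(sort(c(x, y)), collapse = "-"),
                        a[keep], b[keep]))
  expect_setequal(got, want)
})

test_that("zoom levels on a hand-checkable star graph", {
  # center q is the only query gene; 5 leaves touch exactly one query gene
  ed <- edge_df(rep("q", 5), paste0("leaf", 1:5), rep(0.9, 5))
  g <- make_interaction_graph(ed, 0.7)
  expect_length(zoom(g, "q", 1)$nodes, 6L)
  expect_length(zoom(g, "q", 2)$nodes, 1L)
  z3 <- zoom(g, "q", 3)
  expect_equal(z3$nodes, "q")
  expect_equal(igraph::ecount(z3$graph), 0L)
  # two query genes sharing one non-query neighbor: x reaches level 2
  ed2 <- edge_df(c("q1", "q2"), c("x", "x"), c(0.9, 0.9))
  g2 <- make_interaction_graph(ed2, 0.7)
  expect_true("x" %in% zoom(g2, c("q1", "q2"), 2)$nodes)
  expect_error(zoom(g2, character(0), 1), "empty query")
})

test_that("zoom node sets equal exhaustive query-neighbor counting", {
  set.seed(42)
  for (rep in 1:20) {
    genes <- sprintf("n%02d", 1:30)
    n_e <- 60L
    a <- sample(genes, n_e, replace = TRUE)
    b <- sample(genes, n_e, replace = TRUE)
    keep <- a != b
    ed <- edge_df(a[keep], b[keep], runif(sum(keep), 0.71, 1))
    ed <- ed[!duplicated(t(apply(ed[1:2], 1, sort))), ]
    g <- make_interaction_graph(ed, 0.7)
    query <- sample(genes, 8)
    for (lv in 1:3) {
      z <- zoom(g, query, lv)
      expect_equal(sort(z$nodes), oracle_zoom_nodes(ed, query, lv))
    }
    # nesting: L3 subset of L2 subset of L1
    n1 <- zoom(g, query, 1)$nodes
    n2 <- zoom(g, query, 2)$nodes
    n3 <- zoom(g, query, 3)$nodes
    expect_true(all(n3 %in% n2) && all(n2 %in% n1))
    # every non-query L2 node has >= 2 distinct query neighbors
    for (v in setdiff(n2, query)) {
      nb <- igraph::neighbors(g, v)$name
      expect_gte(length(intersect(nb, query)), 2L)
    }
  }
})

test_that("zoom is invariant under edge-list row and endpoint order", {
  set.seed(43)
  genes <- sprintf("n%02d", 1:15)
  ed <- edge_df(sample(genes, 30, TRUE), sample(genes, 30, TRUE),
                runif(30, 0.71, 1))
  ed <- ed[ed$gene_a != ed$gene_b, ]
  query <- sample(genes, 4)
  g1 <- make_interaction_graph(ed, 0.7)
  perm <- sample(nrow(ed))
  ed2 <- edge_df(ed$gene_b[perm], ed$gene_a[perm], ed$confidence[perm])
  g2 <- make_interaction_graph(ed2, 0.7)
  for (lv in 1:3)
    expect_setequal(zoom(g1, query, lv)$nodes, zoom(g2, query, lv)$nodes)
})

test_that("components: sorting rule and union-find agreement", {
  # edgeless query network: one singleton component per node
  ed <- edge_df(paste0("a", 1:5), paste0("b", 1:5), rep(0.9, 5))
  g <- make_interaction_graph(ed, 0.7)
  z <- zoom(g, paste0("a", 1:5), 3)
  expect_length(z$components, 5L)
  expect_true(all(lengths(z$components) == 1L))
  # two disjoint triangles -> sizes [3, 3]
  ed <- edge_df(c("a", "b", "c", "x", "y", "z"),
                c("b", "c", "a", "y", "z", "x"), rep(0.9, 6))
  g <- make_interaction_graph(ed, 0.7)
  z <- zoom(g, c("a", "b", "c", "x", "y", "z"), 3)
  expect_equal(lengths(z$components), c(3L, 3L))
  expect_equal(z$components[[1]], c("a", "b", "c"))  # tie: smallest member
  # random graphs against union-find
  set.seed(44)
  for (rep in 1:10) {
    genes <- sprintf("n%02d", 1:20)
    ed <- edge_df(sample(genes, 25, TRUE), sample(genes, 25, TRUE),
                  runif(25, 0.71, 1))
    ed <- ed[ed$gene_a != ed$gene_b, ]
    g <- make_interaction_graph(ed, 0.7)
    z <- zoom(g, genes, 3)
    nodes <- igraph::V(g)$name
    expect_equal(z$components, oracle_components(ed, nodes))
  }
})

test_that("seed-gene view queries the seed plus its in-list partners", {
  ed <- edge_df(c("s", "s", "s", "p1", "out"),
                c("p1", "p2", "out", "x", "x"), rep(0.9, 5))
  g <- make_interaction_graph(ed, 0.7)
  z <- seed_gene_zoom(g, "s", within = c("p1", "p2"), level = 3)
  expect_setequal(z$nodes, c("s", "p1", "p2"))
})

test_that("subgraph exports are readable text", {
  ed <- edge_df(c("a", "b"), c("b", "c"), c(0.9, 0.8))
  g <- make_interaction_graph(ed, 0.7)
  z <- zoom(g, c("a", "b", "c"), 3)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(z, sif)
  expect_length(readLines(sif), 2L)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_zoom_graphml(z, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), 2L)
  js <- withr::local_tempfile(fileext = ".json")
  write_components_json(z, js)
  doc <- jsonlite::read_json(js)
  expect_equal(doc$n_nodes, 3L)
  expect_equal(doc$components[[1]]$size, 3L)
})
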