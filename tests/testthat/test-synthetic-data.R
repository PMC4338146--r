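test_that("config validation: probabilities, blocks, mandatory seed", {
  tis <- paste0("T", 1:4)
  expect_error(simulation_config(10, tis, c(0, 0.5, 0.3, 0.1, 0.05),
                                 seed = 1),
               "sum to 1")
  expect_error(simulation_config(10, tis, c(0, 0.6, 0.3, 0.08, 0.02)),
               "seed")
  expect_error(simulation_config(
    10, tis, c(0, 0.6, 0.3, 0.08, 0.02),
    blocks = list(tissue_block("A", c("T1", "T2"), 0.5),
                  tissue_block("B", c("T2", "T3"), 0.5)), seed = 1),
    "disjoint")
  # marginals infeasible against the forced never-expressed fraction
  cfg <- simulation_config(100, tis, c(0, 0.1, 0.6, 0.2, 0.1),
                           never_expressed_fraction = 0.3, seed = 1)
  expect_error(generate_annotation_matrix(cfg), "infeasible")
})

test_that("generated matrices are valid, deterministic, and seed-sensitive", {
  cfg <- preset_table1(seed = 7, n_genes = 150)
  m1 <- generate_annotation_matrix(cfg)
  m2 <- generate_annotation_matrix(cfg)
  expect_identical(m1$states, m2$states)  # pure function of (config, seed)
  m3 <- generate_annotation_matrix(preset_table1(seed = 8, n_genes = 150))
  expect_false(identical(m1$states, m3$states))
  # passes the store's own validation and the summary invariant
  s <- score_summary(m1)
  expect_true(all(s$na + s$negative + s$express == 150))
  # forced never-expressed genes show no expressed call anywhere
  never <- attr(m1, "never_expressed")
  expect_length(never, round(0.165 * 150))
  expect_false(any(m1$states[never, ] %in% c("weak", "medium", "strong")))
})

test_that("marginal state frequencies are recovered at large n", {
  tis <- paste0("T", 1:3)
  target <- c(na = 0, negative = 0.6, weak = 0.3, medium = 0.08,
              strong = 0.02)
  cfg <- simulation_config(5000, tis, target, never_expressed_fraction = 0.1,
                          seed = 101)
  m <- generate_annotation_matrix(cfg)
  s <- score_summary(m)
  for (st in names(target))
    expect_true(all(abs(s[[st]] / 5000 - target[[st]]) < 0.02),
                label = paste("frequency recovery for", st))
})

test_that("correlation strength 0 gives near-zero inter-tissue Spearman", {
  tis <- paste0("T", 1:4)
  cfg <- simulation_config(
    5000, tis, c(0, 0.5, 0.3, 0.15, 0.05),
    blocks = list(tissue_block("A", tis, 0)),
    never_expressed_fraction = 0, seed = 102)
  m <- generate_annotation_matrix(cfg)
  rho <- spearman_matrix(encode_ordinal(m))
  off <- rho[upper.tri(rho)]
  expect_true(all(abs(off) < 0.05))
})

test_that("within-block correlation exceeds between-block at strength 1", {
  tis <- paste0("T", 1:6)
  cfg <- simulation_config(
    2000, tis, c(0, 0.5, 0.3, 0.15, 0.05),
    blocks = list(tissue_block("A", tis[1:3], 1),
                  tissue_block("B", tis[4:6], 1)),
    never_expressed_fraction = 0, seed = 103)
  m <- generate_annotation_matrix(cfg)
  rho <- spearman_matrix(encode_ordinal(m))
  within <- c(rho[1, 2], rho[1, 3], rho[2, 3], rho[4, 5], rho[4, 6], rho[5, 6])
  between <- as.vector(rho[1:3, 4:6])
  expect_gt(min(within), max(between))
})

test_that("interactome generator: modularity, determinism, edge counts", {
  genes <- sprintf("g%03d", 1:60)
  # inter_p = 0: thresholded components stay inside planted modules
  ed <- generate_interactome(genes, n_modules = 3, intra_p = 0.4,
                             inter_p = 1e-9, seed = 11)
  modules <- attr(ed, "modules")
  g <- make_interaction_graph(ed, 0.7)
  for (comp in component_sets_for_test(g))
    expect_length(unique(modules[comp]), 1L)
  # reproducible byte-for-byte
  ed2 <- generate_interactome(genes, n_modules = 3, intra_p = 0.4,
                              inter_p = 1e-9, seed = 11)
  expect_identical(ed, ed2)
  # intra edge count within 3 SD of its binomial expectation
  ed3 <- generate_interactome(genes, n_modules = 3, intra_p = 0.2,
                              inter_p = 0, seed = 12)
  n_pairs <- 3 * choose(20, 2)
  expected <- 0.2 * n_pairs
  sd3 <- 3 * sqrt(n_pairs * 0.2 * 0.8)
  expect_lt(abs(nrow(ed3) - expected), sd3)
})

test_that("GO and morbidmap generators hit their configured fractions", {
  genes <- sprintf("g%04d", 1:1000)
  go <- generate_go_table(genes, nogo_fraction = 0.2, seed = 13)
  expect_length(attr(go, "nogo_genes"), 200L)  # exact by construction
  nf <- nogo_fraction(gene_list(genes), go)
  expect_equal(nf$count, 200L)
  # same seed -> identical files
  tmpa <- withr::local_tempfile(); tmpb <- withr::local_tempfile()
  write_go_table(generate_go_table(genes, seed = 14), tmpa)
  write_go_table(generate_go_table(genes, seed = 14), tmpb)
  expect_identical(readLines(tmpa), readLines(tmpb))
  # morbid linkage at the default fraction over 623 genes
  g623 <- sprintf("g%04d", 1:623)
  mm <- generate_morbidmap(g623, morbid_fraction = 0.12, seed = 15)
  linked <- attr(disease_links(gene_list(g623), mm), "n_linked")
  expect_true(linked %in% c(74L, 75L))
})

test_that("fixture emission writes matched, parseable files plus manifest", {
  dir <- withr::local_tempdir()
  cfg <- preset_table1(seed = 21, n_genes = 80)
  paths <- simulate_fixtures(dir, seed = 21, config = cfg)
  m <- load_annotations(paths$annotations)
  expect_equal(dim(m), c(80L, 25L))
  g <- load_edges(paths$edges, threshold = 0.7)
  expect_gt(igraph::ecount(g), 0L)
  go <- load_go_table(paths$go)
  expect_true(all(canonical_gene(go$gene) %in% canonical_gene(ann_genes(m))))
  mm <- load_morbidmap(paths$morbidmap)
  expect_true(all(canonical_gene(mm$gene) %in% canonical_gene(ann_genes(m))))
  manifest <- jsonlite::read_json(paths$manifest)
  expect_equal(manifest$n_genes, 80L)
  expect_equal(manifest$never_expressed_fraction, 0.165)
})

test_that("sieve intersection size on generated data matches expectation", {
  # five "sensory" tissues in separate blocks at strength 0, so the
  # expressed indicators are independent across tissues given the forced
  # never-expressed subset; the intersection size is then a sum of
  # independent Bernoulli draws over the non-forced genes
  tis <- paste0("T", 1:5)
  marg <- c(0, 0.45, 0.3, 0.18, 0.07)
  f <- 0.165
  n <- 4000
  cfg <- simulation_config(n, tis, marg, never_expressed_fraction = f,
                          seed = 104)
  m <- generate_annotation_matrix(cfg)
  q <- paste(sprintf("%s is expressed", tis), collapse = " AND ")
  got <- length(apply_sieve(m, q))
  p_expr_live <- (1 - marg[1]) * (sum(marg[3:5]) / (1 - marg[1])) / (1 - f)
  p_all <- p_expr_live^5
  mu <- n * (1 - f) * p_all
  sd3 <- 3 * sqrt(n * (1 - f) * p_all * (1 - p_all))
  expect_lt(abs(got - mu), sd3)
})
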