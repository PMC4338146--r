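# Synthetic data generators: annotation matrices with planted tissue blocks
# and controlled marginals, modular interactomes, GO tables and morbidmaps.
# All generators are pure functions of (config, seed).

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed
#'
#' A splittable counter scheme: each generator in a multi-fixture simulation
#' consumes `child_seed(master, k)` for a distinct counter `k`, so adding a
#' generator never perturbs the draws of the others. Values stay below
#' 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param k Non-negative integer counter.
#' @return An integer seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) %% 1e6 * 2017 + as.numeric(k) * 7919 + 1) %%
               2147483647)
}

#' Planted tissue block specification
#'
#' A group of tissues sharing a latent per-gene intensity: within-block
#' correlation `strength` mixes the shared latent with tissue-specific
#' noise. Blocks are disjoint; tissues not covered by any block behave as
#' singleton blocks (independent).
#'
#' @param label Block label.
#' @param tissues Character vector of member tissue ids.
#' @param strength Within-block correlation strength in `[0, 1]`.
#' @return An object of class `tissue_block`.
#' @export
tissue_block <- function(label, tissues, strength) {
  stopifnot(is.character(tissues), length(tissues) >= 1L,
            is.numeric(strength), strength >= 0, strength <= 1)
  structure(list(label = label, tissues = tissues, strength = strength),
            class = "tissue_block")
}

#' Simulation configuration for a synthetic annotation matrix
#'
#' @param n_genes Number of genes.
#' @param tissues Tissue panel: character vector of ids or data frame with
#'   `tissue_id` and `name`.
#' @param marginals Per-tissue target state frequencies: a matrix with one
#'   row per tissue and columns `na`, `negative`, `weak`, `medium`,
#'   `strong`, each row summing to 1 (within 1e-9); or a single 5-vector
#'   recycled over tissues. These are *overall* marginals - the generator
#'   hits them in expectation whatever the never-expressed fraction.
#' @param blocks List of [tissue_block()] specifications (disjoint).
#' @param never_expressed_fraction Fraction of genes forced negative in
#'   every tissue (default 0.165, the observed fraction of genes with no
#'   ISH signal anywhere in the 2000-gene screen).
#' @param seed Mandatory integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes, tissues, marginals, blocks = list(),
                              never_expressed_fraction = 0.165, seed) {
  if (missing(seed)) stop("`seed` is mandatory for reproducibility")
  if (is.data.frame(tissues)) {
    panel <- as.data.frame(tissues)[, c("tissue_id", "name")]
  } else {
    panel <- data.frame(tissue_id = as.character(tissues),
                        name = as.character(tissues),
                        stringsAsFactors = FALSE)
  }
  nt <- nrow(panel)
  if (is.vector(marginals))
    marginals <- matrix(marginals, nrow = nt, ncol = 5L, byrow = TRUE)
  marginals <- as.matrix(marginals)
  colnames(marginals) <- EXPRESSION_STATES
  rownames(marginals) <- panel$tissue_id
  if (any(abs(rowSums(marginals) - 1) > 1e-9))
    stop("each tissue's marginal state frequencies must sum to 1")
  if (any(marginals < 0)) stop("negative marginal frequency")
  f <- never_expressed_fraction
  stopifnot(f >= 0, f <= 1)
  bl_tissues <- unlist(lapply(blocks, `[[`, "tissues"))
  if (anyDuplicated(bl_tissues)) stop("tissue blocks must be disjoint")
  if (!all(bl_tissues %in% panel$tissue_id))
    stop("block tissues absent from the panel")
  structure(list(n_genes = as.integer(n_genes), tissues = panel,
                 marginals = marginals, blocks = blocks,
                 never_expressed_fraction = f, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic annotation matrix
#'
#' Latent-factor-plus-threshold construction: each gene draws one latent
#' intensity per block; a tissue in a block with strength `s` observes
#' `sqrt(s) * block_latent + sqrt(1 - s) * noise`, a standard normal, which
#' is then cut at thresholds computed from the tissue's cumulative marginal
#' frequencies. A `never_expressed_fraction` subset of genes is forced
#' negative everywhere (the thresholds of the remaining genes are adjusted
#' so the overall marginals still hold); not-analyzed cells are sprinkled at
#' each tissue's `na` marginal. Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return An `annotation_matrix`. The forced never-expressed gene ids are
#'   attached as attribute `never_expressed`.
#' @export
generate_annotation_matrix <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  panel <- config$tissues
  nt <- nrow(panel)
  f <- config$never_expressed_fraction
  # feasibility: forced-negative mass must fit inside each tissue's
  # negative-given-analyzed marginal
  p_na <- config$marginals[, "na"]
  cond <- config$marginals[, c("negative", "weak", "medium", "strong")] /
    (1 - p_na)
  q_neg <- (cond[, "negative"] - f) / (1 - f)
  if (any(q_neg < -1e-12))
    stop("infeasible marginals: negative-given-analyzed frequency below the ",
         "never-expressed fraction for tissue(s) ",
         paste(panel$tissue_id[q_neg < -1e-12], collapse = ", "))
  q_neg <- pmax(q_neg, 0)
  q <- cbind(negative = q_neg,
             weak = cond[, "weak"] / (1 - f),
             medium = cond[, "medium"] / (1 - f),
             strong = cond[, "strong"] / (1 - f))
  q <- q / rowSums(q)  # guard tiny numeric drift
  # block membership: uncovered tissues are singleton blocks
  block_of <- stats::setNames(rep(NA_integer_, nt), panel$tissue_id)
  strength <- stats::setNames(rep(0, nt), panel$tissue_id)
  for (b in seq_along(config$blocks)) {
    bl <- config$blocks[[b]]
    block_of[bl$tissues] <- b
    strength[bl$tissues] <- bl$strength
  }
  nb <- length(config$blocks)
  singles <- which(is.na(block_of))
  block_of[singles] <- nb + seq_along(singles)
  n_blocks <- nb + length(singles)
  with_seed(config$seed, {
    genes <- sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))
    never <- sort(sample.int(n, round(f * n)))
    z_block <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
    states <- matrix("negative", n, nt,
                     dimnames = list(genes, panel$tissue_id))
    live <- setdiff(seq_len(n), never)
    for (t in seq_len(nt)) {
      s <- strength[t]
      z <- sqrt(s) * z_block[, block_of[t]] + sqrt(1 - s) * stats::rnorm(n)
      cuts <- stats::qnorm(cumsum(q[t, ])[1:3])
      lab <- c("negative", "weak", "medium", "strong")[
        findInterval(z[live], cuts) + 1L]
      states[live, t] <- lab
      # n.a. cells replace any call, forced-negative genes included
      na_hit <- stats::runif(n) < p_na[t]
      states[na_hit, t] <- "na"
    }
    out <- annotation_matrix(states, tissues = panel)
    attr(out, "never_expressed") <- genes[never]
    out
  })
}

#' Build an annotation matrix realizing given per-tissue counts
#'
#' Constructs a matrix whose per-tissue state counts exactly equal a count
#' table (columns `na`, `negative`, `weak`, `medium`, `strong`, each tissue
#' row summing to the same gene total). Cells are laid out deterministically
#' per tissue; tissue columns are independent, so only the per-tissue
#' margins are meaningful. Useful for re-entering published per-tissue
#' summary tables as a concrete fixture.
#'
#' @param counts Data frame with `tissue_id`, optional `name`, and the five
#'   state count columns (e.g. [tissue_counts_table()]).
#' @return An `annotation_matrix`.
#' @export
matrix_from_tissue_counts <- function(counts) {
  counts <- as.data.frame(counts)
  need <- c("tissue_id", EXPRESSION_STATES)
  if (!all(need %in% names(counts)))
    stop("`counts` needs columns: ", paste(need, collapse = ", "))
  tot <- rowSums(counts[, EXPRESSION_STATES])
  if (length(unique(tot)) != 1L)
    stop("state counts must sum to the same gene total for every tissue")
  n <- tot[1L]
  genes <- sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))
  states <- vapply(seq_len(nrow(counts)), function(t)
    rep(EXPRESSION_STATES, times = as.integer(counts[t, EXPRESSION_STATES])),
    character(n))
  dimnames(states) <- list(genes, counts$tissue_id)
  panel <- data.frame(tissue_id = counts$tissue_id,
                      name = if ("name" %in% names(counts)) counts$name
                             else counts$tissue_id,
                      stringsAsFactors = FALSE)
  annotation_matrix(states, tissues = panel)
}

#' Simulation preset mirroring the published 25-tissue screen
#'
#' A [simulation_config()] whose per-tissue marginals equal the published
#' count table divided by the 2000-gene total, with the observed 16.5%
#' never-expressed fraction and three planted tissue blocks reflecting the
#' three main dendrogram branches of the screen: A, the inner-ear
#' vestibular/semicircular tissues (T12-T18); B, mesenchymal/skeletal and
#' other mesoderm-derived structures; C, nervous and skin-derived tissues.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (default 2000).
#' @param block_strength Within-block correlation strength shared by the
#'   three blocks (default 0.6).
#' @return A `simulation_config`.
#' @export
preset_table1 <- function(seed, n_genes = 2000, block_strength = 0.6) {
  tab <- tissue_counts_table()
  marg <- as.matrix(tab[, EXPRESSION_STATES]) / 2000
  panel <- data.frame(tissue_id = tab$tissue_id, name = tab$name,
                      stringsAsFactors = FALSE)
  blocks <- list(
    tissue_block("A", paste0("T", 12:18), block_strength),
    tissue_block("B", paste0("T", c(2, 4, 5, 6, 8, 9, 10, 11, 19, 24)),
                 block_strength),
    tissue_block("C", paste0("T", c(1, 3, 7, 20, 21, 22, 23, 25)),
                 block_strength))
  simulation_config(n_genes = n_genes, tissues = panel, marginals = marg,
                    blocks = blocks, never_expressed_fraction = 0.165,
                    seed = seed)
}

#' Generate a modular interactome edge list
#'
#' Planted-partition graph: genes are split into contiguous modules; each
#' intra-module pair is an edge with probability `intra_p`, each
#' inter-module pair with probability `inter_p` (< `intra_p`). Confidences
#' are drawn uniformly from `conf_intra` / `conf_inter`, chosen so that
#' thresholding at 0.7 retains mostly intra-module edges.
#'
#' @param genes Character vector of gene ids, or an integer count.
#' @param n_modules Number of planted modules.
#' @param intra_p,inter_p Edge probabilities (`intra_p > inter_p`).
#' @param conf_intra,conf_inter Length-2 confidence ranges.
#' @param seed Integer seed.
#' @return Data frame with columns `gene_a`, `gene_b`, `confidence`;
#'   attribute `modules` maps gene to module index.
#' @export
generate_interactome <- function(genes, n_modules = 5, intra_p = 0.2,
                                 inter_p = 0.01,
                                 conf_intra = c(0.72, 0.99),
                                 conf_inter = c(0.30, 0.80), seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (is.numeric(genes) && length(genes) == 1L)
    genes <- sprintf("g%0*d", max(4L, nchar(genes)), seq_len(genes))
  n <- length(genes)
  stopifnot(n >= 2L, intra_p > inter_p)
  module <- stats::setNames(
    as.integer(cut(seq_len(n), breaks = n_modules, labels = FALSE)), genes)
  with_seed(seed, {
    ij <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
    same <- module[ij[, 1]] == module[ij[, 2]]
    p <- ifelse(same, intra_p, inter_p)
    hit <- stats::runif(nrow(ij)) < p
    ij <- ij[hit, , drop = FALSE]; same <- same[hit]
    conf <- ifelse(same,
                   stats::runif(nrow(ij), conf_intra[1], conf_intra[2]),
                   stats::runif(nrow(ij), conf_inter[1], conf_inter[2]))
    out <- data.frame(gene_a = genes[ij[, 1]], gene_b = genes[ij[, 2]],
                      confidence = round(conf, 3),
                      stringsAsFactors = FALSE)
    attr(out, "modules") <- module
    out
  })
}

#' Generate a synthetic gene-to-GO table
#'
#' A fixed `nogo_fraction` of the genes receives no term (exact count by
#' construction, `round(nogo_fraction * n)`); every other gene draws
#' `1 + Poisson(mean_terms - 1)` distinct terms from a synthetic term pool
#' with aspects sampled from `aspect_probs`.
#'
#' @param genes Character vector of gene ids.
#' @param nogo_fraction Fraction of genes with no term (default 0.183, the
#'   observed no-GO fraction of the 2000-gene screen).
#' @param n_terms Size of the term pool.
#' @param mean_terms Mean number of terms per annotated gene (>= 1).
#' @param aspect_probs Named probabilities over aspects.
#' @param seed Integer seed.
#' @return A `go_table`; attribute `nogo_genes` lists the unannotated genes.
#' @export
generate_go_table <- function(genes, nogo_fraction = 0.183, n_terms = 40,
                              mean_terms = 2,
                              aspect_probs = c(MF = 0.6, BP = 0.3, CC = 0.1),
                              seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  n <- length(genes)
  stopifnot(n >= 1L, nogo_fraction >= 0, nogo_fraction <= 1, mean_terms >= 1)
  with_seed(seed, {
    term_id <- sprintf("GO:%07d", seq_len(n_terms))
    term_name <- sprintf("synthetic molecular activity %03d", seq_len(n_terms))
    term_aspect <- sample(names(aspect_probs), n_terms, replace = TRUE,
                          prob = aspect_probs)
    nogo <- sort(sample.int(n, round(nogo_fraction * n)))
    rows <- lapply(setdiff(seq_len(n), nogo), function(i) {
      k <- min(1L + stats::rpois(1L, mean_terms - 1), n_terms)
      t <- sample.int(n_terms, k)
      data.frame(gene = genes[i], term_id = term_id[t],
                 term_name = term_name[t], aspect = term_aspect[t],
                 stringsAsFactors = FALSE)
    })
    out <- as_go_table(do.call(rbind, rows))
    attr(out, "nogo_genes") <- genes[nogo]
    out
  })
}

#' Generate a synthetic morbidmap
#'
#' A `round(morbid_fraction * n)` subset of the genes is linked to synthetic
#' disorders of 1-3 genes each, emitted in the morbidmap pipe dialect via
#' [write_morbidmap()].
#'
#' @param genes Character vector of gene ids.
#' @param morbid_fraction Fraction of genes carrying a disorder record
#'   (default 0.12, the approximate disease-linked fraction reported for the
#'   sensory co-expressed gene set).
#' @param seed Integer seed.
#' @return A `morbidmap` data frame (one row per disorder-gene pair).
#' @export
generate_morbidmap <- function(genes, morbid_fraction = 0.12, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  n <- length(genes)
  stopifnot(n >= 1L, morbid_fraction >= 0, morbid_fraction <= 1)
  with_seed(seed, {
    linked <- genes[sort(sample.int(n, round(morbid_fraction * n)))]
    recs <- list()
    i <- 1L; k <- 0L
    while (i <= length(linked)) {
      k <- k + 1L
      size <- sample.int(3L, 1L)
      members <- linked[i:min(i + size - 1L, length(linked))]
      recs[[k]] <- data.frame(
        disorder = sprintf("Synthetic disorder %03d (3)", k),
        gene = members,
        mim = sprintf("%06d", 600000 + k),
        cyto = sprintf("%dq2%d", (k %% 20) + 1L, k %% 10),
        stringsAsFactors = FALSE)
      i <- i + size
    }
    out <- if (length(recs)) do.call(rbind, recs) else
      data.frame(disorder = character(), gene = character(),
                 mim = character(), cyto = character())
    class(out) <- c("morbidmap", "data.frame")
    out
  })
}

#' Emit a matched set of synthetic fixture files
#'
#' Generates an annotation matrix (from a preset or supplied config), an
#' interactome edge list over the same genes, a GO table and a morbidmap,
#' writes them under `dir` in the module file dialects, and records every
#' parameter in a `manifest.json`. Each component consumes its own
#' [child_seed()] of the master seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param config Optional `simulation_config`; default [preset_table1()]
#'   with `child_seed(seed, 1)`.
#' @return Invisible named list of the written file paths.
#' @export
simulate_fixtures <- function(dir, seed, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config)) config <- preset_table1(seed = child_seed(seed, 1))
  ann <- generate_annotation_matrix(config)
  genes <- ann_genes(ann)
  edges <- generate_interactome(genes, seed = child_seed(seed, 2))
  go <- generate_go_table(genes, seed = child_seed(seed, 3))
  mm <- generate_morbidmap(genes, seed = child_seed(seed, 4))
  paths <- list(
    annotations = file.path(dir, "annotations.tsv"),
    edges = file.path(dir, "interactome.tsv"),
    go = file.path(dir, "go_table.tsv"),
    morbidmap = file.path(dir, "morbidmap.txt"),
    manifest = file.path(dir, "manifest.json"))
  write_annotations(ann, paths$annotations)
  write_edges(edges, paths$edges)
  write_go_table(go, paths$go)
  write_morbidmap(mm, paths$morbidmap)
  manifest <- list(
    master_seed = seed,
    n_genes = config$n_genes,
    never_expressed_fraction = config$never_expressed_fraction,
    blocks = lapply(config$blocks, function(b)
      list(label = b$label, tissues = b$tissues, strength = b$strength)),
    marginals = as.data.frame(config$marginals),
    files = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
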