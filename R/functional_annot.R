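# GO fold-enrichment ratios between two gene lists, no-GO fractions, and
# morbidmap disease linkage.

#' Load a gene-to-GO-term table
#'
#' TSV with header `gene<TAB>term_id<TAB>term_name<TAB>aspect`. Term ids must
#' be well-formed (`GO:` followed by seven digits); aspects are free short
#' codes such as MF/BP/CC. A gene absent from the table (or mapped to no
#' term) counts as "NoGO".
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `go_table`.
#' @export
load_go_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, quote = "")
  need <- c("gene", "term_id", "term_name", "aspect")
  if (!all(need %in% names(df)))
    stop("GO table needs columns: ", paste(need, collapse = ", "))
  as_go_table(df[, need])
}

#' @rdname load_go_table
#' @param df Data frame with columns `gene`, `term_id`, `term_name`, `aspect`.
#' @export
as_go_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  bad <- !grepl("^GO:[0-9]{7}$", df$term_id)
  if (any(bad))
    stop("malformed GO term id(s): ",
         paste(utils::head(unique(df$term_id[bad]), 3), collapse = ", "))
  class(df) <- c("go_table", "data.frame")
  df
}

#' Write a GO table to TSV
#' @param go A `go_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_go_table <- function(go, path) {
  utils::write.table(as.data.frame(go), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

go_members <- function(x) {
  if (inherits(x, "gene_list")) x$members else as.character(x)
}

#' GO fold enrichment between two gene lists
#'
#' For every GO term attached to at least one gene of the union of the two
#' lists (after the aspect filter), computes the percentage of genes of list
#' A carrying the term, the same percentage for list B, and their ratio
#' (fold). Fold > 1 means over-representation in A, fold < 1
#' under-representation. The ratio is a descriptive statistic; no
#' significance machinery is attached. When a term is absent from B the fold
#' is undefined (reported as `Inf`) and such records are excluded from the
#' sorted ranking unless requested.
#'
#' @param list_a,list_b `gene_list` objects (or character vectors); both
#'   non-empty.
#' @param go A `go_table`.
#' @param aspect Aspect filter; defaults to `"MF"` (molecular function).
#'   `NULL` keeps all aspects.
#' @param min_pct Report-level display threshold: keep records where either
#'   percentage reaches this value (default 0 = keep all).
#' @param sort `"desc"` (default), `"asc"` or `"none"` on fold.
#' @param include_undefined Keep records with undefined fold (`pct_b == 0`);
#'   default `FALSE`.
#' @return Data frame with columns `term_id`, `term_name`, `aspect`,
#'   `count_a`, `count_b`, `pct_a`, `pct_b`, `fold`.
#' @export
fold_enrichment <- function(list_a, list_b, go, aspect = "MF", min_pct = 0,
                            sort = c("desc", "asc", "none"),
                            include_undefined = FALSE) {
  sort <- match.arg(sort)
  stopifnot(inherits(go, "go_table"))
  a <- go_members(list_a); b <- go_members(list_b)
  if (!length(a) || !length(b)) stop("both gene lists must be non-empty")
  tab <- as.data.frame(go)
  if (!is.null(aspect)) tab <- tab[tab$aspect %in% aspect, , drop = FALSE]
  tab$key <- canonical_gene(tab$gene)
  tab <- tab[!duplicated(paste(tab$key, tab$term_id)), , drop = FALSE]
  ka <- unique(canonical_gene(a)); kb <- unique(canonical_gene(b))
  tab <- tab[tab$key %in% union(ka, kb), , drop = FALSE]
  if (!nrow(tab)) {
    out <- data.frame(term_id = character(), term_name = character(),
                      aspect = character(), count_a = integer(),
                      count_b = integer(), pct_a = numeric(),
                      pct_b = numeric(), fold = numeric())
    return(out)
  }
  terms <- unique(tab[, c("term_id", "term_name", "aspect")])
  ca <- table(tab$term_id[tab$key %in% ka])
  cb <- table(tab$term_id[tab$key %in% kb])
  terms$count_a <- as.integer(ca[terms$term_id]); terms$count_a[is.na(terms$count_a)] <- 0L
  terms$count_b <- as.integer(cb[terms$term_id]); terms$count_b[is.na(terms$count_b)] <- 0L
  terms$pct_a <- 100 * terms$count_a / length(ka)
  terms$pct_b <- 100 * terms$count_b / length(kb)
  terms$fold <- ifelse(terms$pct_b > 0, terms$pct_a / terms$pct_b, Inf)
  if (min_pct > 0)
    terms <- terms[terms$pct_a >= min_pct | terms$pct_b >= min_pct, ,
                   drop = FALSE]
  if (!include_undefined) terms <- terms[is.finite(terms$fold), , drop = FALSE]
  if (sort != "none")
    terms <- terms[order(terms$fold, decreasing = (sort == "desc")), ,
                   drop = FALSE]
  rownames(terms) <- NULL
  terms
}

#' Fraction of a gene list without GO annotation
#'
#' @param list A `gene_list` or character vector; non-empty.
#' @param go A `go_table`.
#' @return List with `count` (genes carrying no term, any aspect) and
#'   `percentage` (relative to the list size, one decimal).
#' @export
nogo_fraction <- function(list, go) {
  stopifnot(inherits(go, "go_table"))
  members <- go_members(list)
  if (!length(members)) stop("empty gene list")
  keys <- unique(canonical_gene(members))
  annotated <- unique(canonical_gene(go$gene))
  count <- sum(!keys %in% annotated)
  list(count = count, percentage = pct1(count, length(keys)))
}

#' Load a morbidmap-style disorder table
#'
#' Accepts the pipe dialect `disorder|gene symbols|MIM|cyto` (gene symbols
#' comma-separated) or the same four fields tab-separated. Multi-gene rows
#' are indexed under every listed symbol. Rows with fewer than two fields or
#' no gene symbol are skipped with a warning.
#'
#' @param path Path to the morbidmap text file.
#' @return Data frame of class `morbidmap` with one row per
#'   (disorder, gene) pair: columns `disorder`, `gene`, `mim`, `cyto`.
#' @export
load_morbidmap <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  recs <- list()
  skipped <- 0L
  for (k in seq_along(lines)) {
    ln <- lines[k]
    fields <- if (grepl("|", ln, fixed = TRUE))
      strsplit(ln, "|", fixed = TRUE)[[1]] else
      strsplit(ln, "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    genes <- if (length(fields) >= 2L)
      trimws(strsplit(fields[2L], ",", fixed = TRUE)[[1]]) else character()
    genes <- genes[nzchar(genes)]
    if (length(fields) < 2L || !nzchar(fields[1L]) || !length(genes)) {
      skipped <- skipped + 1L
      next
    }
    recs[[length(recs) + 1L]] <- data.frame(
      disorder = fields[1L], gene = genes,
      mim = if (length(fields) >= 3L) fields[3L] else NA_character_,
      cyto = if (length(fields) >= 4L) fields[4L] else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    warning(skipped, " malformed morbidmap record(s) skipped")
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(disorder = character(), gene = character(),
               mim = character(), cyto = character())
  class(out) <- c("morbidmap", "data.frame")
  out
}

#' Write a morbidmap table in the pipe dialect
#'
#' One line per disorder: `disorder|gene1, gene2|MIM|cyto`.
#'
#' @param mm A `morbidmap` data frame (per-gene rows are re-grouped by
#'   disorder/MIM).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_morbidmap <- function(mm, path) {
  df <- as.data.frame(mm)
  if (!nrow(df)) { writeLines(character(), path); return(invisible(path)) }
  key <- paste(df$disorder, df$mim, sep = "\r")
  lines <- vapply(unique(key), function(k) {
    rows <- df[key == k, , drop = FALSE]
    sprintf("%s|%s|%s|%s", rows$disorder[1L],
            paste(rows$gene, collapse = ", "),
            if (is.na(rows$mim[1L])) "" else rows$mim[1L],
            if (is.na(rows$cyto[1L])) "" else rows$cyto[1L])
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Disease linkage for a gene list
#'
#' Joins a gene list against a morbidmap: returns one row per
#' (gene, disorder) pair for the list genes having at least one disorder
#' record. The number of distinct linked genes is attached as attribute
#' `n_linked`.
#'
#' @param list A `gene_list` or character vector.
#' @param mm A `morbidmap`.
#' @return Data frame with columns `gene` (list spelling), `disorder`,
#'   `mim`, `cyto`; attribute `n_linked`.
#' @export
disease_links <- function(list, mm) {
  stopifnot(inherits(mm, "morbidmap"))
  members <- go_members(list)
  keys <- canonical_gene(members)
  mmk <- canonical_gene(mm$gene)
  hit <- mmk %in% keys
  out <- data.frame(
    gene = members[match(mmk[hit], keys)],
    disorder = mm$disorder[hit],
    mim = mm$mim[hit],
    cyto = mm$cyto[hit],
    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$disorder), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_linked") <- length(unique(canonical_gene(out$gene)))
  out
}
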