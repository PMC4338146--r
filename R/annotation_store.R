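# Five-state ordinal annotation store: the gene x tissue grid every other
# module consumes.

#' Canonical expression-state vocabulary
#'
#' The five mutually exclusive per-cell calls of an ISH annotation matrix, in
#' ordinal order. `"na"` means the signal could not be determined reliably
#' (not analyzed) and carries no ordinal value; the remaining four states map
#' to the numeric codes 0 (negative), 2 (weak), 3 (medium) and 4 (strong)
#' used by all rank-based computations. The gap between negative and weak is
#' deliberate: it is the scoring convention of the source annotation system.
#'
#' @format Character vector of length 5.
#' @export
EXPRESSION_STATES <- c("na", "negative", "weak", "medium", "strong")

#' @rdname EXPRESSION_STATES
#' @format NULL
#' @export
EXPRESSED_STATES <- c("weak", "medium", "strong")

# ordinal codes; "na" is masked (NA) and excluded from rank computations
ORDINAL_CODES <- c(na = NA_real_, negative = 0, weak = 2, medium = 3, strong = 4)

# controlled keyword vocabulary for expression-pattern comments
KEYWORD_VOCAB <- c("patchy", "spotted", "generalized")

# input aliases -> canonical tokens (matching is lowercase + trimmed)
STATE_ALIASES <- c(
  "na" = "na", "n.a." = "na", "n.a" = "na", "not analyzed" = "na",
  "not_analyzed" = "na",
  "negative" = "negative", "neg" = "negative",
  "weak" = "weak", "w" = "weak",
  "medium" = "medium", "med" = "medium", "m" = "medium",
  "strong" = "strong", "str" = "strong", "s" = "strong"
)

#' Canonicalize expression-state tokens
#'
#' Maps case-insensitive input tokens (including accepted aliases such as
#' `"n.a."` or `"neg"`) to the canonical lowercase vocabulary of
#' [EXPRESSION_STATES]. Unknown tokens yield `NA`.
#'
#' @param x Character vector of state tokens.
#' @return Character vector of canonical tokens, `NA` where unrecognized.
#' @export
canonical_state <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(STATE_ALIASES[key])
  out
}

#' Canonical gene identifier for joins
#'
#' Gene identifiers are matched case-insensitively across modules; the
#' original spelling is preserved for display.
#'
#' @param x Character vector of gene identifiers.
#' @return Lowercased, trimmed identifiers.
#' @export
canonical_gene <- function(x) tolower(trimws(as.character(x)))

#' Construct an annotation matrix
#'
#' An `annotation_matrix` holds one five-state call per (gene, tissue) pair:
#' a character matrix of canonical state tokens with gene rownames and
#' tissue-id colnames, plus a tissue panel (id and display name) and optional
#' per-cell keyword comments. Every cell holds exactly one state; absence of
#' a call is encoded as `"na"`, never omitted.
#'
#' @param states Character matrix (genes x tissues) of state tokens; aliases
#'   are accepted and canonicalized. Must have unique rownames (genes,
#'   case-insensitively unique) and colnames (tissue ids).
#' @param tissues Optional data frame with columns `tissue_id` and `name`
#'   describing the panel in column order; defaults to ids with `name = id`.
#' @param comments Optional data frame with columns `gene`, `tissue`,
#'   `keywords` (comma-separated, drawn from the controlled vocabulary
#'   patchy/spotted/generalized) and `free_text`. Stored as opaque metadata.
#' @return An object of class `annotation_matrix`.
#' @seealso [load_annotations()], [score_summary()], [encode_ordinal()]
#' @export
annotation_matrix <- function(states, tissues = NULL, comments = NULL) {
  if (!is.matrix(states) || !is.character(states))
    stop("`states` must be a character matrix")
  if ((nrow(states) > 0L && is.null(rownames(states))) ||
      is.null(colnames(states)))
    stop("`states` must have gene rownames and tissue colnames")
  if (is.null(rownames(states))) rownames(states) <- character(0)
  canon <- canonical_state(states)
  bad <- which(is.na(canon) | is.na(states))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(states))
    stop(sprintf("unknown state token '%s' at gene '%s', tissue '%s'",
                 states[bad[1L]], rownames(states)[i[1L]],
                 colnames(states)[i[2L]]))
  }
  states[] <- canon
  genes <- rownames(states)
  dup <- duplicated(canonical_gene(genes))
  if (any(dup))
    stop("duplicate gene identifier(s): ",
         paste(unique(genes[dup]), collapse = ", "))
  if (is.null(tissues)) {
    tissues <- data.frame(tissue_id = colnames(states),
                          name = colnames(states),
                          stringsAsFactors = FALSE)
  }
  if (!all(c("tissue_id", "name") %in% names(tissues)))
    stop("`tissues` needs columns tissue_id and name")
  tissues <- as.data.frame(tissues)[, c("tissue_id", "name")]
  if (anyDuplicated(tissues$tissue_id))
    stop("duplicate tissue_id in panel")
  if (!identical(as.character(tissues$tissue_id), colnames(states)))
    stop("tissue panel does not match state matrix columns (order matters)")
  if (!is.null(comments)) {
    comments <- as.data.frame(comments)
    need <- c("gene", "tissue")
    if (!all(need %in% names(comments)))
      stop("`comments` needs columns gene and tissue")
    if (!"keywords" %in% names(comments)) comments$keywords <- ""
    if (!"free_text" %in% names(comments)) comments$free_text <- ""
    kw <- unlist(strsplit(comments$keywords, ",", fixed = TRUE))
    kw <- trimws(kw[nzchar(trimws(kw))])
    if (length(kw) && !all(kw %in% KEYWORD_VOCAB))
      stop("comment keywords outside controlled vocabulary (",
           paste(KEYWORD_VOCAB, collapse = ", "), "): ",
           paste(setdiff(kw, KEYWORD_VOCAB), collapse = ", "))
    if (!all(canonical_gene(comments$gene) %in% canonical_gene(genes)))
      stop("comment rows reference unknown genes")
    if (!all(comments$tissue %in% tissues$tissue_id))
      stop("comment rows reference unknown tissues")
  }
  structure(list(states = states, tissues = tissues, comments = comments),
            class = "annotation_matrix")
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("annotation_matrix: %d genes x %d tissues\n",
              nrow(x$states), ncol(x$states)))
  tab <- table(factor(x$states, levels = EXPRESSION_STATES))
  cat("  cells:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (!is.null(x$comments))
    cat(sprintf("  comments: %d\n", nrow(x$comments)))
  invisible(x)
}

#' @export
dim.annotation_matrix <- function(x) dim(x$states)

#' Genes and tissues of an annotation matrix
#' @param x An `annotation_matrix`.
#' @return Character vector of gene ids (original spelling) or tissue ids.
#' @export
ann_genes <- function(x) rownames(x$states)

#' @rdname ann_genes
#' @export
ann_tissues <- function(x) colnames(x$states)

#' Read an annotation matrix from TSV
#'
#' The file format is one header row `gene<TAB>T1<TAB>...`, one row per gene,
#' cells holding state tokens (case-insensitive; aliases such as `n.a.` are
#' accepted). Row and column order are preserved.
#'
#' @param path Path to the TSV file.
#' @param tissues Optional tissue panel data frame passed to
#'   [annotation_matrix()].
#' @return An `annotation_matrix`.
#' @export
load_annotations <- function(path, tissues = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) != 1L)
    stop(sprintf("ragged TSV: line %d has %d fields, expected %d",
                 which(nf != nf[1L])[1L], nf[nf != nf[1L]][1L], nf[1L]))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("annotation TSV needs a gene column and >=1 tissue")
  genes <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- genes
  canon <- canonical_state(m)
  bad <- which(is.na(canon))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(m))
    stop(sprintf("unknown state token '%s' at row %d (gene '%s'), column '%s'",
                 m[bad[1L]], i[1L], genes[i[1L]], colnames(m)[i[2L]]))
  }
  annotation_matrix(m, tissues = tissues)
}

#' Write an annotation matrix to TSV
#'
#' Writes canonical lowercase state tokens; a load/write/load round trip
#' yields an identical matrix.
#'
#' @param x An `annotation_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(x, path) {
  stopifnot(inherits(x, "annotation_matrix"))
  df <- data.frame(gene = rownames(x$states), x$states,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Percentage to one decimal, IEEE round-to-nearest on the double value.
# This is the formatting rule (C "%.1f") that reproduces the published
# per-tissue percentage tables cell-for-cell; both exact-decimal
# half-to-even and R's round() disagree with some published cells.
pct1 <- function(count, total) as.numeric(sprintf("%.1f", 100 * count / total))

#' Per-tissue expression summary
#'
#' Counts and percentages of each state per tissue, plus the "expressed"
#' margin (weak + medium + strong). Percentages are relative to the total
#' gene count and rounded to one decimal.
#'
#' @param x An `annotation_matrix`.
#' @return A data frame of class `tissue_summary`, one row per tissue, with
#'   columns `tissue_id`, `name`, the five state counts, `express`, and the
#'   matching `pct_*` columns. For every tissue
#'   `na + negative + express == n_genes`.
#' @export
score_summary <- function(x) {
  stopifnot(inherits(x, "annotation_matrix"))
  n <- nrow(x$states)
  if (n == 0L) stop("empty annotation matrix")
  counts <- t(apply(x$states, 2L, function(col)
    table(factor(col, levels = EXPRESSION_STATES))))
  out <- data.frame(
    tissue_id = x$tissues$tissue_id,
    name = x$tissues$name,
    stringsAsFactors = FALSE
  )
  for (s in EXPRESSION_STATES) out[[s]] <- as.integer(counts[, s])
  out$express <- out$weak + out$medium + out$strong
  for (s in c(EXPRESSION_STATES, "express"))
    out[[paste0("pct_", s)]] <- pct1(out[[s]], n)
  attr(out, "n_genes") <- n
  class(out) <- c("tissue_summary", "data.frame")
  out
}

#' Write a tissue summary to TSV
#' @param s A `tissue_summary` from [score_summary()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(s, path) {
  utils::write.table(as.data.frame(s), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Ordinal encoding of an annotation matrix
#'
#' Maps negative/weak/medium/strong to 0/2/3/4 and masks not-analyzed cells
#' as `NA`. The encoding is the input to all rank-based computations; masked
#' cells never enter them.
#'
#' @param x An `annotation_matrix`.
#' @return Numeric matrix with the same dimnames as the state grid.
#' @export
encode_ordinal <- function(x) {
  stopifnot(inherits(x, "annotation_matrix"))
  out <- matrix(ORDINAL_CODES[x$states], nrow = nrow(x$states),
                dimnames = dimnames(x$states))
  out
}

#' The published 25-tissue expression count table
#'
#' Per-tissue counts of the five states over the 2000-gene E14.5 ear and
#' sensory-organ ISH screen, together with the published percentages, as
#' shipped in `inst/extdata`. Useful as a reference fixture: a synthetic
#' matrix with exactly these per-tissue counts can be built with
#' [matrix_from_tissue_counts()].
#'
#' @return Data frame with one row per tissue: counts (`na`, `negative`,
#'   `weak`, `medium`, `strong`, `express`), published percentages (`pct_*`)
#'   and the tissue `name`.
#' @export
tissue_counts_table <- function() {
  path <- system.file("extdata", "tissue_expression_counts.tsv",
                      package = "ishannot", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
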