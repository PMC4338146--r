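# Boolean "sieve" filtering: tissue-level expression predicates combined with
# AND/OR, and set algebra on the resulting gene lists.

#' Construct a gene list
#'
#' A named set of gene identifiers with provenance (the query or set
#' operation that produced it). Members are de-duplicated case-insensitively,
#' keeping the first-seen spelling.
#'
#' @param members Character vector of gene ids.
#' @param name Optional list name.
#' @param provenance Optional free-form provenance (stored, not interpreted).
#' @return An object of class `gene_list`.
#' @export
gene_list <- function(members, name = NULL, provenance = NULL) {
  members <- as.character(members)
  members <- members[!duplicated(canonical_gene(members))]
  structure(list(name = name, members = members, provenance = provenance),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("gene_list%s: %d genes\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              length(x$members)))
  if (length(x$members))
    cat(" ", paste(utils::head(x$members, 10L), collapse = ", "),
        if (length(x$members) > 10L) "..." else "", "\n")
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$members)

#' Read / write plain-text gene lists
#'
#' One identifier per line; blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @param name Optional name for the list (defaults to the file name).
#' @return [read_gene_list()] returns a `gene_list`; [write_gene_list()]
#'   returns `path` invisibly.
#' @export
read_gene_list <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  gene_list(lines[nzchar(lines)],
            name = if (is.null(name)) basename(path) else name,
            provenance = list(type = "file", path = path))
}

#' @rdname read_gene_list
#' @param x A `gene_list`.
#' @export
write_gene_list <- function(x, path) {
  stopifnot(inherits(x, "gene_list"))
  writeLines(x$members, path)
  invisible(path)
}

# ---- query grammar ---------------------------------------------------------
# expr      := term (OR term)*
# term      := factor (AND factor)*
# factor    := '(' expr ')' | predicate
# predicate := TISSUE ('is'|'in') states
# states    := STATE | '{' STATE (',' STATE)* '}' | 'expressed'
# "expressed" is sugar for {weak, medium, strong}.  "na" matches a cell only
# when listed explicitly: not-analyzed is never silently treated as a level.

sieve_tokenize <- function(expr) {
  pat <- "\\(|\\)|\\{|\\}|,|[^()\\{\\},[:space:]]+"
  m <- gregexpr(pat, expr, perl = TRUE)[[1]]
  if (m[1L] == -1L) return(data.frame(tok = character(), pos = integer()))
  data.frame(tok = regmatches(expr, list(m))[[1]], pos = as.integer(m),
             stringsAsFactors = FALSE)
}

#' Parse a sieve query expression
#'
#' Parses the infix text form of a Boolean tissue-expression query into a
#' query tree of class `sieve_query`. Leaves are `(tissue, allowed states)`
#' predicates written `T9 is weak`, `T22 in {medium,strong}` or
#' `T9 is expressed` (sugar for weak/medium/strong); internal nodes are
#' `AND`/`OR` with the usual precedence (AND binds tighter) and parentheses.
#'
#' @param expr Query text.
#' @param tissues Optional character vector of valid tissue ids; when given,
#'   leaf tissues are validated at parse time.
#' @return A `sieve_query`.
#' @examples
#' q <- parse_query("T9 is expressed AND T14 in {medium,strong}")
#' @export
parse_query <- function(expr, tissues = NULL) {
  toks <- sieve_tokenize(expr)
  i <- 0L
  n <- nrow(toks)
  peek <- function() if (i < n) toks$tok[i + 1L] else NA_character_
  pos <- function() if (i < n) toks$pos[i + 1L] else nchar(expr) + 1L
  take <- function() { i <<- i + 1L; toks$tok[i] }
  fail <- function(msg) stop(sprintf("sieve query syntax error at position %d: %s",
                                     pos(), msg), call. = FALSE)
  kw <- function(x, what) !is.na(x) && tolower(x) == what

  parse_states <- function() {
    t <- peek()
    if (is.na(t)) fail("expected a state")
    if (t == "{") {
      take()
      states <- character()
      repeat {
        s <- take()
        if (is.na(s) || s %in% c(",", "{", "}", "(", ")"))
          fail("expected a state token inside {...}")
        cs <- canonical_state(s)
        if (is.na(cs)) fail(paste0("unknown state '", s, "'"))
        states <- c(states, cs)
        nxt <- take()
        if (is.na(nxt)) fail("unterminated {...}")
        if (nxt == "}") break
        if (nxt != ",") fail("expected ',' or '}'")
      }
      return(unique(states))
    }
    s <- take()
    if (tolower(s) == "expressed") return(EXPRESSED_STATES)
    cs <- canonical_state(s)
    if (is.na(cs)) fail(paste0("unknown state '", s, "'"))
    cs
  }

  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) fail("expected a predicate or '('")
    if (t == "(") {
      take()
      node <- parse_expr()
      if (!identical(peek(), ")")) fail("expected ')'")
      take()
      return(node)
    }
    tissue <- take()
    if (tissue %in% c(")", "}", ",", "{")) fail("expected a tissue id")
    if (!is.null(tissues) && !tissue %in% tissues)
      stop(sprintf("unknown tissue id '%s' in sieve query", tissue),
           call. = FALSE)
    op <- take()
    if (is.na(op) || !(tolower(op) %in% c("is", "in")))
      fail("expected 'is' or 'in' after tissue id")
    states <- parse_states()
    structure(list(type = "leaf", tissue = tissue, states = states),
              class = "sieve_query")
  }

  parse_term <- function() {
    kids <- list(parse_factor())
    while (kw(peek(), "and")) { take(); kids <- c(kids, list(parse_factor())) }
    if (length(kids) == 1L) return(kids[[1L]])
    structure(list(type = "op", op = "and", children = kids),
              class = "sieve_query")
  }

  parse_expr <- function() {
    kids <- list(parse_term())
    while (kw(peek(), "or")) { take(); kids <- c(kids, list(parse_term())) }
    if (length(kids) == 1L) return(kids[[1L]])
    structure(list(type = "op", op = "or", children = kids),
              class = "sieve_query")
  }

  out <- parse_expr()
  if (i < n) fail(paste0("unexpected token '", peek(), "'"))
  out
}

#' Render a sieve query back to its text form
#' @param q A `sieve_query`.
#' @return A single character string.
#' @export
format_query <- function(q) {
  stopifnot(inherits(q, "sieve_query"))
  if (q$type == "leaf") {
    st <- if (length(q$states) == 1L) q$states else
      paste0("{", paste(q$states, collapse = ","), "}")
    return(paste(q$tissue, if (length(q$states) == 1L) "is" else "in", st))
  }
  parts <- vapply(q$children, function(ch) {
    s <- format_query(ch)
    if (ch$type == "op" && ch$op != q$op) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", toupper(q$op), " "))
}

#' @export
print.sieve_query <- function(x, ...) {
  cat("sieve_query:", format_query(x), "\n")
  invisible(x)
}

# evaluate a query tree to a logical vector over the matrix's genes
eval_query <- function(x, q) {
  if (q$type == "leaf") {
    if (!q$tissue %in% colnames(x$states))
      stop(sprintf("sieve query references tissue '%s' absent from the matrix",
                   q$tissue))
    return(x$states[, q$tissue] %in% q$states)
  }
  vals <- lapply(q$children, function(ch) eval_query(x, ch))
  Reduce(if (q$op == "and") `&` else `|`, vals)
}

#' Apply a sieve query to an annotation matrix
#'
#' Returns exactly the genes whose per-tissue states satisfy the Boolean
#' tree. A not-analyzed cell satisfies a predicate only when `"na"` is
#' explicitly among the allowed states.
#'
#' @param x An `annotation_matrix`.
#' @param query A `sieve_query`, or query text parsed with [parse_query()]
#'   against the matrix's tissue panel.
#' @param name Optional name for the resulting list.
#' @return A `gene_list` whose provenance records the query text.
#' @export
apply_sieve <- function(x, query, name = NULL) {
  stopifnot(inherits(x, "annotation_matrix"))
  if (is.character(query)) query <- parse_query(query, tissues = ann_tissues(x))
  stopifnot(inherits(query, "sieve_query"))
  sel <- eval_query(x, query)
  gene_list(ann_genes(x)[sel], name = name,
            provenance = list(type = "sieve", query = format_query(query)))
}

#' Combine gene lists with set algebra
#'
#' Union, intersection or complement on canonical (case-insensitive) gene
#' ids. `complement` returns `universe \\ (union of lists)` and requires a
#' universe list.
#'
#' @param lists A `gene_list` or a list of them.
#' @param op One of `"union"`, `"intersection"`, `"complement"`.
#' @param universe Universe `gene_list`, required for `"complement"`.
#' @param name Optional name for the result.
#' @return A `gene_list`; provenance records the operands and operation.
#' @export
combine_lists <- function(lists, op = c("union", "intersection", "complement"),
                          universe = NULL, name = NULL) {
  op <- match.arg(op)
  if (inherits(lists, "gene_list")) lists <- list(lists)
  stopifnot(length(lists) >= 1L,
            all(vapply(lists, inherits, logical(1), "gene_list")))
  keysets <- lapply(lists, function(l) canonical_gene(l$members))
  # first-seen spelling per canonical id
  all_members <- unlist(lapply(lists, `[[`, "members"), use.names = FALSE)
  if (!is.null(universe)) {
    stopifnot(inherits(universe, "gene_list"))
    all_members <- c(all_members, universe$members)
  }
  spell <- all_members[!duplicated(canonical_gene(all_members))]
  names(spell) <- canonical_gene(spell)
  keys <- switch(op,
    union = Reduce(union, keysets),
    intersection = Reduce(intersect, keysets),
    complement = {
      if (is.null(universe))
        stop("complement requires a `universe` gene list")
      setdiff(canonical_gene(universe$members), Reduce(union, keysets))
    })
  gene_list(unname(spell[keys]), name = name,
            provenance = list(type = "combine", op = op,
                              operands = lapply(lists, `[[`, "name")))
}

# ---- saved query store -----------------------------------------------------

query_to_list <- function(q) {
  if (q$type == "leaf")
    list(tissue = q$tissue, states = as.list(q$states))
  else
    list(op = q$op, children = lapply(q$children, query_to_list))
}

list_to_query <- function(l) {
  if (!is.null(l$tissue))
    structure(list(type = "leaf", tissue = l$tissue,
                   states = unlist(l$states)), class = "sieve_query")
  else
    structure(list(type = "op", op = l$op,
                   children = lapply(l$children, list_to_query)),
              class = "sieve_query")
}

#' Save and load named sieve queries
#'
#' Queries are stored as a JSON document mapping name to query tree, so
#' saved pattern searches can be re-run later.
#'
#' @param queries Named list of `sieve_query` objects.
#' @param path JSON file path.
#' @return [save_queries()] returns `path` invisibly; [load_queries()]
#'   returns a named list of `sieve_query` objects.
#' @export
save_queries <- function(queries, path) {
  stopifnot(is.list(queries), length(names(queries)) == length(queries),
            all(nzchar(names(queries))))
  doc <- lapply(queries, query_to_list)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_queries
#' @export
load_queries <- function(path) {
  doc <- jsonlite::read_json(path)
  lapply(doc, list_to_query)
}
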