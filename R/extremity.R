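#' Gene extremities
#'
#' Every gene `g` is an oriented marker with two extremities, a tail `gt`
#' and a head `gh`. Internally an extremity is an integer code: gene `g`
#' has tail `2g - 1` and head `2g`, which gives the deterministic total
#' order (by gene, tail before head) used everywhere for canonical output.
#'
#' @param x extremity tokens such as `"1h"` or `"3t"` (character), or
#'   integer codes, which are validated and returned unchanged.
#' @return integer vector of extremity codes.
#' @examples
#' ext(c("1t", "1h", "3h"))
#' ext_token(ext("5t"))
#' @export
ext <- function(x) {
  if (is.numeric(x)) {
    code <- as.integer(x)
    if (any(is.na(code)) || any(code < 1L))
      stop("extremity codes must be positive integers")
    return(code)
  }
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([0-9]+)([ht])$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed extremity token(s): ", paste(x[bad], collapse = ", "))
  gene <- as.integer(vapply(m, `[`, "", 2L))
  if (any(gene < 1L)) stop("gene identifiers are 1-based positive integers")
  head <- vapply(m, `[`, "", 3L) == "h"
  2L * gene - 1L + as.integer(head)
}

#' @rdname ext
#' @param code integer extremity codes.
#' @export
ext_token <- function(code) {
  code <- as.integer(code)
  paste0(ext_gene(code), ifelse(code %% 2L == 0L, "h", "t"))
}

#' @rdname ext
#' @export
ext_gene <- function(code) (as.integer(code) + 1L) %/% 2L

# extremity joined to `code` by the gene edge of the augmented genome graph
gene_partner <- function(code) {
  code <- as.integer(code)
  code + ifelse(code %% 2L == 0L, -1L, 1L)
}

# Coerce adjacency input to a canonical m x 2 integer matrix of codes.
# Accepted: NULL; character vector, one adjacency per element, two tokens
# separated by whitespace or comma; list of length-2 vectors; 2-column
# matrix of tokens or codes.
as_adj_matrix <- function(x) {
  if (is.null(x) || length(x) == 0L)
    return(matrix(integer(), ncol = 2L))
  if (is.matrix(x)) {
    if (ncol(x) != 2L) stop("adjacency matrix must have 2 columns")
    m <- cbind(ext(x[, 1L]), ext(x[, 2L]))
  } else if (is.list(x)) {
    if (any(lengths(x) != 2L)) stop("each adjacency must have 2 extremities")
    m <- t(vapply(x, function(p) ext(p), integer(2L)))
  } else if (is.character(x)) {
    toks <- strsplit(trimws(x), "[,[:space:]]+")
    if (any(lengths(toks) != 2L))
      stop("each adjacency string must contain exactly 2 extremity tokens")
    m <- t(vapply(toks, function(p) ext(p), integer(2L)))
  } else stop("cannot interpret adjacencies of class ", class(x)[1L])
  canon_adj(m)
}

# per-row sorted (smaller extremity first), rows in lexicographic order;
# duplicates preserved (multiset ordering)
canon_adj <- function(m) {
  if (nrow(m) == 0L) return(matrix(integer(), ncol = 2L))
  swap <- m[, 1L] > m[, 2L]
  m[swap, ] <- m[swap, c(2L, 1L), drop = FALSE]
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Render adjacencies as canonical token strings
#'
#' `adj_strings` formats each row of an adjacency matrix as
#' `"<smaller> <larger>"` token pairs (e.g. `"1h 3h"`); `adj_key` collapses
#' a whole adjacency set into a single canonical string, handy as a
#' deterministic identity for genomes and edge sets.
#'
#' @param m 2-column integer matrix of extremity codes (e.g. the `adj`
#'   field of a `genome`), or anything [genome()] accepts as adjacencies.
#' @return character vector (`adj_strings`) or single string (`adj_key`).
#' @examples
#' adj_strings(genome(2, "2t 1h")$adj)
#' @export
adj_strings <- function(m) {
  if (!is.matrix(m)) m <- as_adj_matrix(m)
  if (nrow(m) == 0L) return(character())
  paste(ext_token(m[, 1L]), ext_token(m[, 2L]))
}

#' @rdname adj_strings
#' @export
adj_key <- function(m) {
  if (!is.matrix(m)) m <- as_adj_matrix(m)
  paste(adj_strings(canon_adj(m)), collapse = ";")
}
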