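#' Partial multi-genomes (adjacency mixtures)
#'
#' A partial multi-genome is a multiset of adjacencies pooled from several
#' (partial) genomes whose genome of origin is unknown — the situation in
#' bulk sequencing of a heterogeneous tumor, where novel adjacencies are
#' detected but not attributed to subclones. Its genome graph is a
#' multigraph: repeated adjacencies keep their multiplicity and vertex
#' degrees are unbounded a priori.
#'
#' @param n_genes number of genes.
#' @param adjacencies adjacency multiset in any form accepted by
#'   [genome()]; repeated entries are multiplicities, and an extremity may
#'   occur in several adjacencies.
#' @return object of class `multi_genome` with fields `n_genes` and `adj`.
#' @examples
#' m <- multi_genome(2, c("1h 2t", "1h 2t", "2h 1t"))
#' genome_graph(m)$degree
#' @export
multi_genome <- function(n_genes, adjacencies = NULL) {
  n_genes <- as.integer(n_genes)
  if (length(n_genes) != 1L || is.na(n_genes) || n_genes < 0L)
    stop("n_genes must be a single non-negative integer")
  adj <- as_adj_matrix(adjacencies)
  check_extremity_range(adj, n_genes)
  if (any(adj[, 1L] == adj[, 2L]))
    stop("self-pair adjacency: an adjacency joins two distinct extremities")
  structure(list(n_genes = n_genes, adj = adj), class = "multi_genome")
}

#' @export
print.multi_genome <- function(x, ...) {
  cat("partial multi-genome on", x$n_genes, "genes with", nrow(x$adj),
      "adjacencies (multiset)\n")
  if (nrow(x$adj)) {
    tab <- table(adj_strings(x$adj))
    cat(" ", paste0("{", sub(" ", ",", names(tab)), "}",
                    ifelse(tab > 1L, paste0(" x", tab), ""), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Genome graph of a partial multi-genome
#'
#' The multigraph on all `2 n` gene extremities whose edge multiset is the
#' adjacency multiset. The chromatic index of this graph decides whether a
#' k-genome attribution of the mixture exists.
#'
#' @param m a `multi_genome` (a `genome` is accepted and treated as a
#'   trivial mixture).
#' @return list with `n_genes`, `edges` (2-column code matrix, multiset),
#'   `degree` (integer vector over all extremities) and `max_degree`.
#' @export
genome_graph <- function(m) {
  stopifnot(inherits(m, c("multi_genome", "genome")))
  deg <- tabulate(as.vector(m$adj), nbins = 2L * m$n_genes)
  list(n_genes = m$n_genes, edges = m$adj, degree = deg,
       max_degree = if (length(deg)) max(deg) else 0L)
}

# --- plain-text adjacency format --------------------------------------------

#' Read and write the adjacency file format
#'
#' The format is plain text: a header line `genes <n>`, then one adjacency
#' per line as two whitespace-separated extremity tokens (`1h 3h`); `#`
#' starts a comment. For single genomes a repeated adjacency line is an
#' error; in multi-genome files repetition encodes multiplicity.
#'
#' @param path file path.
#' @param multi read as a `multi_genome` (multiset) instead of a `genome`.
#' @return `read_adjacencies`: a `genome` or `multi_genome`.
#' @examples
#' f <- tempfile()
#' write_adjacencies(genome(2, "1h 2t"), f)
#' read_adjacencies(f)
#' @export
read_adjacencies <- function(path, multi = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !grepl("^genes[[:space:]]+[0-9]+$", lines[1L]))
    stop("missing header line 'genes <n>' in ", path)
  n <- as.integer(sub("^genes[[:space:]]+", "", lines[1L]))
  body <- lines[-1L]
  if (!multi && anyDuplicated(vapply(strsplit(body, "[[:space:]]+"),
                                     function(p) paste(sort(p), collapse = " "),
                                     "")))
    stop("duplicate adjacency line in single-genome file ", path)
  if (multi) multi_genome(n, body) else genome(n, body)
}

#' @rdname read_adjacencies
#' @param g a `genome` or `multi_genome` to write.
#' @return `write_adjacencies`: `path`, invisibly.
#' @export
write_adjacencies <- function(g, path) {
  stopifnot(inherits(g, c("genome", "multi_genome")))
  writeLines(c(paste("genes", g$n_genes), adj_strings(g$adj)), path)
  invisible(path)
}

# --- GRIMM-style signed permutations ----------------------------------------

#' Build a genome from signed gene orders
#'
#' Each chromosome is a sequence of signed gene identifiers terminated by
#' `$` (linear) or `@` (circular), as in GRIMM. The adjacency joins the
#' right extremity of each gene to the left extremity of its successor,
#' where right(+g) = head, left(+g) = tail, right(-g) = tail,
#' left(-g) = head; `@` additionally joins the last right extremity to the
#' first left extremity.
#'
#' @param chromosomes character vector, one chromosome per element, e.g.
#'   `c("1 -3 $", "2 4 -5 @")`. Genes must be exactly `1..n`, each used
#'   once.
#' @return a `genome` on `n` genes.
#' @examples
#' from_signed_permutations(c("2 4 -5 @", "1 -3 $"))
#' @export
from_signed_permutations <- function(chromosomes) {
  if (!length(chromosomes)) stop("no chromosomes given")
  seen <- integer()
  adj <- matrix(integer(), ncol = 2L)
  for (line in chromosomes) {
    toks <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
    if (!length(toks) || !toks[length(toks)] %in% c("$", "@"))
      stop("chromosome must end with '$' (linear) or '@' (circular): ", line)
    circ <- toks[length(toks)] == "@"
    genes <- suppressWarnings(as.integer(toks[-length(toks)]))
    if (!length(genes) || any(is.na(genes)) || any(genes == 0L))
      stop("malformed gene token in chromosome: ", line)
    if (any(abs(genes) %in% seen) || anyDuplicated(abs(genes)))
      stop("repeated gene identifier in signed permutation input")
    seen <- c(seen, abs(genes))
    left <- ifelse(genes > 0L, 2L * abs(genes) - 1L, 2L * abs(genes))
    right <- ifelse(genes > 0L, 2L * abs(genes), 2L * abs(genes) - 1L)
    k <- length(genes)
    if (k > 1L)
      adj <- rbind(adj, cbind(right[-k], left[-1L]))
    if (circ)
      adj <- rbind(adj, c(right[k], left[1L]))
  }
  n <- max(seen)
  if (!setequal(seen, seq_len(n)))
    stop("genes must be exactly 1..n; missing: ",
         paste(setdiff(seq_len(n), seen), collapse = " "))
  genome(n, adj)
}

#' Read a GRIMM-style genome file
#'
#' `>name` header lines start a genome; subsequent lines are chromosomes in
#' the syntax of [from_signed_permutations()]. Only the first genome in the
#' file is returned.
#'
#' @param path file path.
#' @return a `genome`.
#' @export
read_grimm <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  headers <- which(startsWith(lines, ">"))
  if (!length(headers)) stop("no '>' header in GRIMM file ", path)
  from <- headers[1L] + 1L
  to <- if (length(headers) > 1L) headers[2L] - 1L else length(lines)
  if (from > to) stop("empty genome in GRIMM file ", path)
  from_signed_permutations(lines[from:to])
}
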