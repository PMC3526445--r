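#' Genomes as adjacency matchings
#'
#' A genome on `n` genes is a set of adjacencies (unordered pairs of gene
#' extremities) in which every extremity occurs at most once: a matching on
#' the `2n` extremities. Extremities in no adjacency are telomeres
#' (chromosome ends). A partial genome is the same object read as "some
#' adjacencies are still missing"; completion operations take the intended
#' chromosomal conditions as an argument.
#'
#' @param n_genes number of genes (positive integer; may be 0 only for the
#'   degenerate empty genome).
#' @param adjacencies adjacencies as a character vector (`"1h 3h"`), a list
#'   of extremity pairs, or a 2-column matrix of tokens/codes.
#' @return an object of class `genome` with fields `n_genes` and `adj`
#'   (canonical 2-column integer matrix of extremity codes).
#' @examples
#' g <- genome(5, c("1h 3h", "5t 2t", "2h 4t", "4h 5h"))
#' telomeres(g)
#' chromosomes(g)
#' @export
genome <- function(n_genes, adjacencies = NULL) {
  n_genes <- as.integer(n_genes)
  if (length(n_genes) != 1L || is.na(n_genes) || n_genes < 0L)
    stop("n_genes must be a single non-negative integer")
  adj <- as_adj_matrix(adjacencies)
  check_extremity_range(adj, n_genes)
  if (any(adj[, 1L] == adj[, 2L]))
    stop("self-pair adjacency: an adjacency joins two distinct extremities")
  occ <- as.vector(adj)
  dup <- occ[duplicated(occ)]
  if (length(dup))
    stop("extremity ", ext_token(dup[1L]),
         " occurs in more than one adjacency (matching violation)")
  structure(list(n_genes = n_genes, adj = adj), class = "genome")
}

check_extremity_range <- function(adj, n_genes) {
  if (nrow(adj) && any(adj > 2L * n_genes))
    stop("extremity ", ext_token(max(adj)), " references a gene beyond n_genes = ",
         n_genes)
  invisible(TRUE)
}

#' @export
print.genome <- function(x, ...) {
  cat("genome on", x$n_genes, "genes with", nrow(x$adj), "adjacencies\n")
  if (nrow(x$adj))
    cat("  A =", paste0("{", sub(" ", ",", adj_strings(x$adj)), "}", collapse = " "), "\n")
  tel <- telomeres(x)
  if (length(tel))
    cat("  telomeres:", paste(ext_token(tel), collapse = " "), "\n")
  invisible(x)
}

#' @export
format.genome <- function(x, ...) adj_key(x$adj)

genome_key <- function(g) paste0("#", adj_key(g$adj))

#' Telomeres of a genome
#'
#' All extremities not covered by any adjacency, in canonical order.
#' For every genome `2 * n_genes = 2 * nrow(adj) + length(telomeres)`.
#'
#' @param g a `genome`.
#' @return integer vector of extremity codes.
#' @export
telomeres <- function(g) {
  stopifnot(inherits(g, "genome"))
  setdiff(seq_len(2L * g$n_genes), as.vector(g$adj))
}

#' Free extremities of a (partial) genome
#'
#' Identical to [telomeres()] but read in the completion setting: degree-0
#' vertices of the genome graph, i.e. extremities still available for new
#' adjacencies.
#' @inheritParams telomeres
#' @export
free_extremities <- function(g) telomeres(g)

# --- augmented genome graph -------------------------------------------------

# Components of the augmented genome graph (gene edges {gt, gh} for every
# gene plus the adjacency edges). Gene edges and adjacency edges are each a
# matching, so components are strictly alternating paths or even cycles.
# Returns components in deterministic order (smallest extremity first), each
# with $extremities (traversal order), $kind ("circular"/"linear"), $genes.
augmented_components <- function(g) {
  n2 <- 2L * g$n_genes
  amate <- rep(NA_integer_, n2)
  if (nrow(g$adj)) {
    amate[g$adj[, 1L]] <- g$adj[, 2L]
    amate[g$adj[, 2L]] <- g$adj[, 1L]
  }
  visited <- logical(n2)
  comps <- list()
  for (v in seq_len(n2)) {
    if (visited[v]) next
    # gather the component (both edge types), then lay out the traversal
    comp <- v
    visited[v] <- TRUE
    frontier <- v
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) for (w in c(gene_partner(u), amate[u])) {
        if (!is.na(w) && !visited[w]) {
          visited[w] <- TRUE
          comp <- c(comp, w)
          nxt <- c(nxt, w)
        }
      }
      frontier <- nxt
    }
    ends <- comp[is.na(amate[comp])]       # path ends lack an adjacency edge
    kind <- if (length(ends)) "linear" else "circular"
    start <- if (length(ends)) min(ends) else min(comp)
    ord <- integer(length(comp))
    cur <- start
    use_gene <- TRUE                       # first step always the gene edge
    for (i in seq_along(ord)) {
      ord[i] <- cur
      cur <- if (use_gene) gene_partner(cur) else amate[cur]
      use_gene <- !use_gene
    }
    comps[[length(comps) + 1L]] <-
      list(extremities = ord, kind = kind,
           genes = sort(unique(ext_gene(ord))))
  }
  comps
}

#' Chromosomes of a genome
#'
#' Connected components of the augmented genome graph (gene edges plus
#' adjacency edges), classified as circular (cycle component) or linear
#' (path component), in deterministic order of smallest extremity.
#'
#' @param g a `genome`.
#' @return object of class `chromosomes`: list of components, each with
#'   `$genes`, `$kind` and `$extremities` (traversal order).
#' @examples
#' chromosomes(genome(1, "1h 1t"))  # one circular single-gene chromosome
#' @export
chromosomes <- function(g) {
  stopifnot(inherits(g, "genome"))
  structure(augmented_components(g), class = "chromosomes")
}

#' @export
print.chromosomes <- function(x, ...) {
  cat(length(x), "chromosome(s)\n")
  for (i in seq_along(x))
    cat(sprintf("  [%d] %s, genes: %s\n", i, x[[i]]$kind,
                paste(x[[i]]$genes, collapse = " ")))
  invisible(x)
}

# --- chromosomal conditions -------------------------------------------------

#' Chromosomal condition sets
#'
#' Validate a set of chromosomal condition flags. The empty set means
#' unrestricted. `"circular"` and `"linear"` are mutually exclusive.
#'
#' @param conditions character vector with values among `"circular"`,
#'   `"linear"`, `"unichromosomal"` (empty for unrestricted).
#' @return the validated, sorted character vector.
#' @export
chrom_conditions <- function(conditions = character()) {
  if (is.null(conditions) || !length(conditions)) return(character())
  conditions <- unique(match.arg(conditions,
    c("circular", "linear", "unichromosomal"), several.ok = TRUE))
  if (all(c("circular", "linear") %in% conditions))
    stop("conditions 'circular' and 'linear' are mutually exclusive")
  sort(conditions)
}

#' Does a genome satisfy a chromosomal condition set?
#'
#' @param g a `genome`.
#' @param conditions see [chrom_conditions()]; the empty set is always
#'   satisfied.
#' @return logical.
#' @export
satisfies <- function(g, conditions = character()) {
  conditions <- chrom_conditions(conditions)
  if (!length(conditions)) return(TRUE)
  kinds <- vapply(chromosomes(g), `[[`, "", "kind")
  ok <- TRUE
  if ("circular" %in% conditions) ok <- ok && all(kinds == "circular")
  if ("linear" %in% conditions) ok <- ok && all(kinds == "linear")
  if ("unichromosomal" %in% conditions) ok <- ok && length(kinds) == 1L
  ok
}

#' Can a partial genome be completed under a condition set?
#'
#' Decides by a structural rule on the augmented genome graph whether some
#' superset of the adjacencies forms a genome satisfying the conditions:
#' unrestricted and `{circular}` are always completable; `{circular,
#' unichromosomal}` requires that either no component is a cycle or the
#' genome is already a single all-gene cycle; `{linear}` and `{linear,
#' unichromosomal}` require no cycle component. `{unichromosomal}` alone is
#' not supported and is rejected.
#'
#' @param g the partial genome (a `genome` object; the matching property is
#'   already enforced by the constructor).
#' @inheritParams satisfies
#' @return logical.
#' @export
is_completable <- function(g, conditions = character()) {
  conditions <- chrom_conditions(conditions)
  if (!length(conditions)) return(TRUE)
  if (identical(conditions, "unichromosomal"))
    stop("condition set {unichromosomal} alone is not supported")
  comps <- chromosomes(g)
  kinds <- vapply(comps, `[[`, "", "kind")
  if (identical(conditions, "circular")) return(TRUE)
  if (setequal(conditions, c("circular", "unichromosomal")))
    return(all(kinds == "linear") ||
             (length(kinds) == 1L && kinds == "circular"))
  # linear (with or without unichromosomal): no cycle may ever be opened
  all(kinds == "linear")
}

# --- completion enumeration (exhaustive oracle) -----------------------------

#' Enumerate all completions of a partial genome
#'
#' Exhaustively enumerates every matching over the free extremities of `g`
#' (including leaving extremities as telomeres), keeping the extensions
#' whose resulting genome satisfies `conditions`. This is the brute-force
#' oracle the exact solvers are validated against; it is exponential and
#' guarded.
#'
#' @inheritParams is_completable
#' @param max_free guard on the number of free extremities (default 10).
#' @return list of `genome` objects (possibly empty).
#' @export
enumerate_completions <- function(g, conditions = character(), max_free = 10L) {
  stopifnot(inherits(g, "genome"))
  conditions <- chrom_conditions(conditions)
  free <- free_extremities(g)
  if (length(free) > max_free)
    stop("too many free extremities (", length(free), ") for exhaustive ",
         "enumeration; guard is ", max_free)
  out <- list()
  recurse <- function(remaining, chosen) {
    if (!length(remaining)) {
      cand <- genome(g$n_genes, rbind(g$adj, chosen))
      if (satisfies(cand, conditions)) out[[length(out) + 1L]] <<- cand
      return(invisible(NULL))
    }
    u <- remaining[1L]
    rest <- remaining[-1L]
    recurse(rest, chosen)                       # u stays a telomere
    for (v in rest)
      recurse(setdiff(rest, v), rbind(chosen, c(u, v)))
  }
  recurse(free, matrix(integer(), ncol = 2L))
  out
}
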