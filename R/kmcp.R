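#' Exact chromatic-index decision for a mixture's genome graph
#'
#' Decides whether the edges of a multigraph can be properly colored with
#' at most `k` colors, i.e. partitioned into `k` matchings. A k-genome
#' attribution of an adjacency mixture exists exactly when this holds.
#' The decision is exact backtracking (largest-degree-first edge order);
#' graphs whose maximum degree already exceeds `k` are rejected without
#' search. Beyond the edge-count guard the answer is `NA` ("undecided")
#' unless the degree bound decides — a heuristic is never reported as an
#' answer.
#'
#' @param g a `multi_genome`, `genome`, or the list returned by
#'   [genome_graph()].
#' @param k positive integer number of colors.
#' @param max_edges guard on the exact search (default 32).
#' @return `TRUE` with attribute `coloring` (integer color per edge, a
#'   witness whose color classes are matchings), `FALSE`, or `NA` when the
#'   guard is exceeded and the degree bound is inconclusive.
#' @examples
#' tri <- multi_genome(3, c("1t 2t", "2t 3t", "3t 1t"))
#' chromatic_index_at_most(tri, 2)  # FALSE
#' chromatic_index_at_most(tri, 3)  # TRUE
#' @export
chromatic_index_at_most <- function(g, k, max_edges = 32L) {
  gg <- if (inherits(g, c("multi_genome", "genome"))) genome_graph(g) else g
  k <- as.integer(k)
  stopifnot(k >= 1L)
  edges <- gg$edges
  m <- nrow(edges)
  if (gg$max_degree > k) return(FALSE)
  if (m == 0L) return(structure(TRUE, coloring = integer()))
  if (m > max_edges) return(NA)
  ord <- order(-(gg$degree[edges[, 1L]] + gg$degree[edges[, 2L]]))
  edges <- edges[ord, , drop = FALSE]
  used <- matrix(FALSE, nrow = 2L * gg$n_genes, ncol = k)
  coloring <- integer(m)
  solve <- function(i, maxc) {
    if (i > m) return(TRUE)
    u <- edges[i, 1L]; v <- edges[i, 2L]
    for (col in seq_len(min(k, maxc + 1L))) {
      if (!used[u, col] && !used[v, col]) {
        used[u, col] <<- TRUE; used[v, col] <<- TRUE
        coloring[i] <<- col
        if (solve(i + 1L, max(maxc, col))) return(TRUE)
        used[u, col] <<- FALSE; used[v, col] <<- FALSE
      }
    }
    FALSE
  }
  if (!solve(1L, 0L)) return(FALSE)
  out <- integer(m)
  out[ord] <- coloring
  structure(TRUE, coloring = out)
}

#' Split a mixture into k genomes (unrestricted k-completion)
#'
#' Promotes the color classes of a proper k-edge-coloring of the mixture's
#' genome graph to genomes: each class is a matching and hence already an
#' (unrestricted) genome, and together the classes contain the mixture
#' multiset.
#'
#' @param m a `multi_genome`.
#' @param k number of genomes.
#' @param max_edges guard forwarded to [chromatic_index_at_most()].
#' @return list of `k` `genome` objects.
#' @export
k_completion <- function(m, k, max_edges = 32L) {
  stopifnot(inherits(m, "multi_genome"))
  res <- chromatic_index_at_most(m, k, max_edges)
  if (is.na(res)) stop("undecided: instance exceeds the exact-search guard")
  if (!res) stop("no ", k, "-completion exists (chromatic index exceeds ",
                 k, ")")
  col <- attr(res, "coloring")
  lapply(seq_len(k), function(i)
    genome(m$n_genes, m$adj[col == i, , drop = FALSE]))
}

# --- mixture trees ----------------------------------------------------------

#' Mixture trees over a reference and k genomes
#'
#' A mixture tree is a rooted tree on the reference plus the `k` genomes in
#' the mixture, rooted at the reference; its value under a pairwise
#' distance is the sum of the distance over tree edges.
#'
#' @param parents integer vector of length `k`: `parents[i]` is the parent
#'   of genome `i`, with `0` denoting the reference root.
#' @return object of class `mixture_tree`.
#' @export
mixture_tree <- function(parents) {
  parents <- as.integer(parents)
  k <- length(parents)
  if (!k || any(is.na(parents)) || any(parents < 0L) || any(parents > k))
    stop("parents must map each of the k genomes to 0 (reference) or 1..k")
  # must be a tree rooted at the reference: every node reaches 0 acyclically
  for (i in seq_len(k)) {
    seen <- integer()
    cur <- i
    while (cur != 0L) {
      if (cur %in% seen) stop("parent vector contains a cycle")
      seen <- c(seen, cur)
      cur <- parents[cur]
    }
  }
  structure(list(parents = parents, k = k), class = "mixture_tree")
}

#' @export
print.mixture_tree <- function(x, ...) {
  lab <- function(i) if (i == 0L) "A" else paste0("G", i)
  cat("mixture tree on {A,", paste0("G", seq_len(x$k), collapse = ","),
      "}: ", paste(vapply(seq_len(x$k), function(i)
        paste0(lab(x$parents[i]), "-", lab(i)), ""), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Value of a mixture tree
#'
#' Sum of a pairwise genome distance over the edges of the tree.
#'
#' @param tree a `mixture_tree`.
#' @param reference the root `genome`.
#' @param genomes list of `k` `genome` objects.
#' @param phi pairwise distance function (default [dcj_distance()]).
#' @return numeric.
#' @export
phi_value <- function(tree, reference, genomes, phi = dcj_distance) {
  stopifnot(inherits(tree, "mixture_tree"), length(genomes) == tree$k)
  nodes <- c(list(reference), genomes)
  sum(vapply(seq_len(tree$k), function(i)
    phi(nodes[[i + 1L]], nodes[[tree$parents[i] + 1L]]), 0))
}

#' Enumerate all labeled mixture trees
#'
#' All labeled trees on the reference plus `k` genomes, rooted at the
#' reference, via Pruefer-sequence enumeration: there are `(k+1)^(k-1)` of
#' them (1 for k = 1, 3 for k = 2 — one branch plus two paths — 16 for
#' k = 3).
#'
#' @param k number of genomes (guarded at 4).
#' @return list of `mixture_tree` objects.
#' @export
enumerate_mixture_trees <- function(k) {
  k <- as.integer(k)
  if (k < 1L || k > 4L) stop("k must be between 1 and 4")
  nv <- k + 1L                        # vertex 1 = reference, 1+i = genome i
  decode <- function(pruefer) {
    degree <- rep(1L, nv)
    for (x in pruefer) degree[x] <- degree[x] + 1L
    edges <- matrix(integer(), ncol = 2L)
    for (x in pruefer) {
      leaf <- min(which(degree == 1L))
      edges <- rbind(edges, c(leaf, x))
      degree[leaf] <- degree[leaf] - 1L
      degree[x] <- degree[x] - 1L
    }
    last <- which(degree == 1L)
    edges <- rbind(edges, last)
    edges
  }
  to_parents <- function(edges) {
    adjacency <- lapply(seq_len(nv), function(i)
      c(edges[edges[, 1L] == i, 2L], edges[edges[, 2L] == i, 1L]))
    parents <- rep(NA_integer_, nv)
    parents[1L] <- 0L
    queue <- 1L
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (w in adjacency[[u]]) if (is.na(parents[w])) {
        parents[w] <- u
        queue <- c(queue, w)
      }
    }
    mixture_tree(parents[-1L] - 1L)   # relabel: vertex 1 -> 0
  }
  if (k == 1L) return(list(mixture_tree(0L)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(nv)), k - 1L)))
  lapply(seq_len(nrow(seqs)), function(i) to_parents(decode(seqs[i, ])))
}

# --- exhaustive exact k-MCP -------------------------------------------------

# all proper colorings of the mixture graph with colors 1..k, deduplicated
# as unordered partitions into classes
all_color_partitions <- function(m, k, max_count = 50000L) {
  gg <- genome_graph(m)
  edges <- gg$edges
  nedg <- nrow(edges)
  if (gg$max_degree > k) return(list())
  if (nedg == 0L)
    return(list(rep(list(matrix(integer(), ncol = 2L)), k)))
  used <- matrix(FALSE, nrow = 2L * gg$n_genes, ncol = k)
  coloring <- integer(nedg)
  out <- new.env(parent = emptyenv())
  recurse <- function(i) {
    if (i > nedg) {
      classes <- lapply(seq_len(k), function(cl)
        edges[coloring == cl, , drop = FALSE])
      key <- paste(sort(vapply(classes, adj_key, "")), collapse = "|")
      if (!exists(key, envir = out, inherits = FALSE))
        assign(key, classes, envir = out)
      return(invisible(NULL))
    }
    u <- edges[i, 1L]; v <- edges[i, 2L]
    for (col in seq_len(k)) {
      if (!used[u, col] && !used[v, col]) {
        used[u, col] <<- TRUE; used[v, col] <<- TRUE
        coloring[i] <<- col
        recurse(i + 1L)
        used[u, col] <<- FALSE; used[v, col] <<- FALSE
      }
    }
    if (length(ls(out)) > max_count)
      stop("too many colorings for exhaustive enumeration")
    invisible(NULL)
  }
  recurse(1L)
  mget(ls(out), envir = out)
}

#' Exhaustive exact solver for the k-minimum completion problem
#'
#' Minimizes the mixture-tree value over every proper k-edge-coloring of
#' the mixture's genome graph, every condition-satisfying completion of
#' every color class, and every labeled mixture tree. Purely exponential
#' and guarded; this is the ground-truth solver the polynomial algorithms
#' and the hardness constructions are checked against.
#'
#' @param m a `multi_genome` mixture.
#' @param reference the reference `genome`.
#' @param k number of genomes in the mixture.
#' @param conditions chromosomal condition set imposed on the completed
#'   genomes (empty = unrestricted).
#' @param phi pairwise distance (default [dcj_distance()]).
#' @param max_n,max_k guards (defaults 3 and 3). They exist because the
#'   search is exponential; callers may raise them for instances whose
#'   structure keeps the enumeration small (e.g. mixtures whose genome
#'   graph is a disjoint union of even cycles).
#' @param max_free guard forwarded to [enumerate_completions()].
#' @return object of class `kmcp_solution`: list with `valid`, `phi`
#'   (minimum value, `NA` if no valid solution), `tree`, `genomes`,
#'   `classes` (the color classes used), `conditions`.
#' @export
brute_force_kmcp <- function(m, reference, k, conditions = character(),
                             phi = dcj_distance, max_n = 3L, max_k = 3L,
                             max_free = 10L) {
  stopifnot(inherits(m, "multi_genome"), inherits(reference, "genome"))
  conditions <- chrom_conditions(conditions)
  if (m$n_genes != reference$n_genes)
    stop("mixture and reference must be on the same number of genes")
  if (m$n_genes > max_n) stop("n exceeds guard max_n = ", max_n)
  if (k > max_k) stop("k exceeds guard max_k = ", max_k)

  partitions <- all_color_partitions(m, k)
  if (!length(partitions))
    return(structure(list(valid = FALSE, phi = NA_real_, tree = NULL,
                          genomes = NULL, classes = NULL,
                          conditions = conditions),
                     class = "kmcp_solution"))
  trees <- enumerate_mixture_trees(k)

  # memoized pairwise distance
  cache <- new.env(parent = emptyenv())
  phi_memo <- function(a, b) {
    key <- paste(sort(c(genome_key(a), genome_key(b))), collapse = "||")
    if (!exists(key, envir = cache, inherits = FALSE))
      assign(key, phi(a, b), envir = cache)
    get(key, envir = cache, inherits = FALSE)
  }

  best <- NULL
  best_phi <- Inf
  for (classes in partitions) {
    comps <- lapply(classes, function(cl) {
      base <- genome(m$n_genes, cl)
      cands <- enumerate_completions(base, conditions, max_free = max_free)
      cands[!duplicated(vapply(cands, genome_key, ""))]
    })
    if (any(!lengths(comps))) next     # some class not completable under C
    idx <- rep(1L, k)
    repeat {
      genomes <- lapply(seq_len(k), function(i) comps[[i]][[idx[i]]])
      for (tr in trees) {
        val <- phi_value(tr, reference, genomes, phi_memo)
        if (val < best_phi) {
          best_phi <- val
          best <- list(tree = tr, genomes = genomes, classes = classes)
        }
      }
      # advance mixed-radix counter over completion choices
      j <- 1L
      while (j <= k) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= length(comps[[j]])) break
        idx[j] <- 1L
        j <- j + 1L
      }
      if (j > k) break
    }
  }
  if (is.null(best))
    return(structure(list(valid = FALSE, phi = NA_real_, tree = NULL,
                          genomes = NULL, classes = NULL,
                          conditions = conditions),
                     class = "kmcp_solution"))
  structure(list(valid = TRUE, phi = best_phi, tree = best$tree,
                 genomes = best$genomes, classes = best$classes,
                 conditions = conditions),
            class = "kmcp_solution")
}

#' @export
print.kmcp_solution <- function(x, ...) {
  if (!x$valid) {
    cat("k-MCP: no valid solution (no k-completion exists)\n")
    return(invisible(x))
  }
  cat("k-MCP solution: phi =", x$phi, "\n")
  print(x$tree)
  for (i in seq_along(x$genomes)) {
    cat("G", i, ": ", sep = "")
    cat(if (nrow(x$genomes[[i]]$adj))
      paste0("{", sub(" ", ",", adj_strings(x$genomes[[i]]$adj)), "}",
             collapse = " ") else "(empty)", "\n")
  }
  invisible(x)
}
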