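#' Breakpoint graph of two or more genomes
#'
#' The edge-colored multigraph on all `2 n` extremities whose edges are the
#' adjacencies of every input genome, colored by genome of origin. For two
#' genomes every component is a simple path (possibly a single isolated
#' vertex) or a cycle; the double-cut-and-join (DCJ) distance is read off
#' this decomposition.
#'
#' @param genomes list of at least two `genome` objects on the same number
#'   of genes.
#' @return object of class `breakpoint_graph`: list with `n_genes`,
#'   `edges` (data.frame `u`, `v`, `genome`), `components` (data.frame with
#'   `n_vertices`, `n_edges`, `kind` in cycle/path/other), and `membership`
#'   (component id per extremity code).
#' @examples
#' g1 <- genome(2, "1h 2t")
#' g2 <- genome(2, c("1h 2t", "2h 1t"))
#' breakpoint_graph(list(g1, g2))$components
#' @export
breakpoint_graph <- function(genomes) {
  stopifnot(is.list(genomes), length(genomes) >= 2L,
            all(vapply(genomes, inherits, TRUE, "genome")))
  n <- genomes[[1L]]$n_genes
  if (any(vapply(genomes, `[[`, 0L, "n_genes") != n))
    stop("all genomes must be on the same number of genes")
  edges <- do.call(rbind, lapply(seq_along(genomes), function(i) {
    a <- genomes[[i]]$adj
    if (!nrow(a)) return(NULL)
    data.frame(u = a[, 1L], v = a[, 2L], genome = i)
  }))
  if (is.null(edges)) edges <- data.frame(u = integer(), v = integer(),
                                          genome = integer())
  n2 <- 2L * n
  # union-find over extremities
  parent <- seq_len(n2)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    ru <- find(edges$u[i]); rv <- find(edges$v[i])
    if (ru != rv) parent[ru] <- rv
  }
  roots <- vapply(seq_len(n2), find, 0L)
  membership <- match(roots, unique(roots[order(seq_len(n2))]))
  deg <- tabulate(c(edges$u, edges$v), nbins = n2)
  comp_ids <- sort(unique(membership))
  comp <- do.call(rbind, lapply(comp_ids, function(cid) {
    vs <- which(membership == cid)
    ne <- if (nrow(edges)) sum(membership[edges$u] == cid) else 0L
    kind <- if (ne == length(vs) && length(vs) >= 2L && all(deg[vs] == 2L))
      "cycle"
    else if (ne == length(vs) - 1L && all(deg[vs] <= 2L))
      "path"
    else "other"
    data.frame(component = cid, n_vertices = length(vs), n_edges = ne,
               kind = kind)
  }))
  structure(list(n_genes = n, n_genomes = length(genomes), edges = edges,
                 components = comp, membership = membership),
            class = "breakpoint_graph")
}

#' @export
print.breakpoint_graph <- function(x, ...) {
  k <- table(x$components$kind)
  cat("breakpoint graph of", x$n_genomes, "genomes on", x$n_genes, "genes:",
      nrow(x$components), "components (",
      paste(names(k), k, sep = ": ", collapse = ", "), ")\n")
  invisible(x)
}

# cycle count and odd-vertex path count for the two-genome formula
bg_counts <- function(bg) {
  comps <- bg$components
  c(cycles = sum(comps$kind == "cycle"),
    odd_paths = sum(comps$kind == "path" & comps$n_vertices %% 2L == 1L))
}

#' DCJ distance between two genomes
#'
#' `n - c - p/2`, where `c` is the number of cycles and `p` the number of
#' paths with an odd number of vertices in the two-genome breakpoint graph.
#' Isolated extremities count as 1-vertex (odd) paths, which makes the
#' distance of a genome to itself zero even in the presence of telomeres.
#'
#' @param g1,g2 `genome` objects on the same number of genes.
#' @return non-negative integer.
#' @examples
#' dcj_distance(genome(1), genome(1, "1h 1t"))  # one join: distance 1
#' @export
dcj_distance <- function(g1, g2) {
  bg <- breakpoint_graph(list(g1, g2))
  cnt <- bg_counts(bg)
  d <- g1$n_genes - cnt[["cycles"]] - cnt[["odd_paths"]] / 2
  if (d != round(d))
    stop("internal error: non-integral DCJ distance (odd-path parity)")
  as.integer(d)
}

#' All genomes one DCJ operation away
#'
#' Enumerates the results of every double-cut-and-join move: replacing two
#' adjacencies \{p,q\},\{r,s\} by \{p,r\},\{q,s\} or \{p,s\},\{q,r\};
#' rejoining an adjacency with a telomere (either endpoint freed); splitting
#' an adjacency into two telomeres; joining two telomeres. Duplicate
#' resulting genomes are removed; the input itself is never returned.
#'
#' @param g a `genome`.
#' @return list of `genome` objects in deterministic order.
#' @export
dcj_neighbors <- function(g) {
  adj <- g$adj
  tel <- telomeres(g)
  res <- list()
  add <- function(mat) {
    cand <- genome(g$n_genes, mat)
    res[[length(res) + 1L]] <<- cand
  }
  m <- nrow(adj)
  if (m >= 2L) for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    p <- adj[i, 1L]; q <- adj[i, 2L]; r <- adj[j, 1L]; s <- adj[j, 2L]
    rest <- adj[-c(i, j), , drop = FALSE]
    add(rbind(rest, c(p, r), c(q, s)))
    add(rbind(rest, c(p, s), c(q, r)))
  }
  if (m >= 1L && length(tel)) for (i in seq_len(m)) for (r in tel) {
    p <- adj[i, 1L]; q <- adj[i, 2L]
    rest <- adj[-i, , drop = FALSE]
    add(rbind(rest, c(p, r)))   # q freed
    add(rbind(rest, c(q, r)))   # p freed
  }
  if (m >= 1L) for (i in seq_len(m))
    add(adj[-i, , drop = FALSE])            # split into two telomeres
  if (length(tel) >= 2L) {
    pairs <- utils::combn(tel, 2L)
    for (j in seq_len(ncol(pairs)))
      add(rbind(adj, pairs[, j]))           # join two telomeres
  }
  keys <- vapply(res, genome_key, "")
  keep <- !duplicated(keys) & keys != genome_key(g)
  res[keep][order(keys[keep])]
}

#' BFS oracle for the DCJ distance
#'
#' Breadth-first search over [dcj_neighbors()] from `g1` until `g2` is
#' reached. Exponential in `n`; guarded, and used only as an independent
#' cross-check of the closed-form distance.
#'
#' @inheritParams dcj_distance
#' @param max_n guard on the number of genes (default 4).
#' @return non-negative integer.
#' @export
dcj_bfs_distance <- function(g1, g2, max_n = 4L) {
  if (g1$n_genes != g2$n_genes)
    stop("genomes must be on the same number of genes")
  if (g1$n_genes > max_n)
    stop("n = ", g1$n_genes, " exceeds the BFS guard (", max_n, ")")
  target <- genome_key(g2)
  frontier <- list(g1)
  seen <- new.env(parent = emptyenv())
  assign(genome_key(g1), TRUE, envir = seen)
  depth <- 0L
  repeat {
    if (any(vapply(frontier, genome_key, "") == target)) return(depth)
    nxt <- list()
    for (g in frontier) for (nb in dcj_neighbors(g)) {
      k <- genome_key(nb)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        assign(k, TRUE, envir = seen)
        nxt[[length(nxt) + 1L]] <- nb
      }
    }
    if (!length(nxt)) stop("target unreachable (should not happen)")
    frontier <- nxt
    depth <- depth + 1L
  }
}
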