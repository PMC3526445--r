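#' Unrestricted optimal completion of a partial genome
#'
#' Closes every breakpoint-graph path of `B(G, A)` whose first and last
#' edges are both reference adjacencies by joining the path's endpoints;
#' all other free extremities stay telomeres. The result contains `G` and
#' minimizes the DCJ distance to `A` over all matching extensions of `G`.
#'
#' @param g the partial genome (a `genome`).
#' @param ref the reference genome on the same number of genes.
#' @return a `genome` containing `g`.
#' @examples
#' complete_unrestricted(genome(1), genome(1, "1h 1t"))
#' @export
complete_unrestricted <- function(g, ref) {
  stopifnot(inherits(g, "genome"), inherits(ref, "genome"))
  if (g$n_genes != ref$n_genes)
    stop("genomes must be on the same number of genes")
  bg <- breakpoint_graph(list(g, ref))
  closing <- matrix(integer(), ncol = 2L)
  deg <- tabulate(c(bg$edges$u, bg$edges$v), nbins = 2L * g$n_genes)
  paths <- bg$components[bg$components$kind == "path" &
                           bg$components$n_edges >= 1L, , drop = FALSE]
  for (cid in paths$component) {
    vs <- which(bg$membership == cid)
    endpoints <- vs[deg[vs] <= 1L]
    # terminal edges: the single edge incident to each endpoint
    terminal_in_ref <- vapply(endpoints, function(e) {
      hit <- bg$edges$u == e | bg$edges$v == e
      any(hit) && all(bg$edges$genome[hit] == 2L)
    }, TRUE)
    if (length(endpoints) == 2L && all(terminal_in_ref))
      closing <- rbind(closing, endpoints)
  }
  genome(g$n_genes, rbind(g$adj, closing))
}

# --- free-extremities graph -------------------------------------------------

#' Free-extremities graph of a partial genome and circular reference
#'
#' The bicolored multigraph on the free extremities `F(G)`: blue (desired)
#' edges pair the endpoints of each path of the breakpoint graph `B(G, A)`;
#' red (excluded) edges pair the endpoints of each path of the augmented
#' genome graph of `G`. Both edge sets are perfect matchings on `F(G)`, so
#' every component is an even alternating cycle (2-cycles allowed).
#'
#' @param g a partial genome completable to a circular unichromosomal
#'   genome, with at least one free extremity.
#' @param ref the reference genome; must be circular (no telomeres), so
#'   that its adjacency set is a perfect matching.
#' @return object of class `feg`: list with sorted `vertices`, `blue` and
#'   `red` (named lists mapping edge id to endpoint pair), `vblue`/`vred`
#'   (edge id incident to each vertex), `cycles_gained` (breakpoint cycles
#'   recorded by blue updates so far) and `closed`.
#' @export
free_extremities_graph <- function(g, ref) {
  stopifnot(inherits(g, "genome"), inherits(ref, "genome"))
  if (g$n_genes != ref$n_genes)
    stop("genomes must be on the same number of genes")
  if (length(telomeres(ref)))
    stop("reference must be circular: its adjacencies must form a perfect ",
         "matching on all extremities")
  free <- free_extremities(g)
  if (!length(free)) stop("the partial genome has no free extremities")

  # blue: endpoints of paths of B(g, ref)
  bg <- breakpoint_graph(list(g, ref))
  deg <- tabulate(c(bg$edges$u, bg$edges$v), nbins = 2L * g$n_genes)
  blue <- lapply(
    bg$components$component[bg$components$kind == "path"],
    function(cid) {
      vs <- which(bg$membership == cid)
      sort(vs[deg[vs] <= 1L])
    })
  # red: endpoints of paths of the augmented genome graph of g
  red <- lapply(Filter(function(cc) cc$kind == "linear",
                       augmented_components(g)),
                function(cc) sort(range(cc$extremities[c(1L,
                  length(cc$extremities))])))
  new_feg(free, blue, red)
}

new_feg <- function(vertices, blue, red) {
  stopifnot(length(blue) == length(red),
            2L * length(blue) == length(vertices))
  name_edges <- function(edges) {
    names(edges) <- paste0("e", seq_along(edges))
    edges
  }
  blue <- name_edges(blue)
  red <- name_edges(red)
  vmap <- function(edges) {
    v <- character()
    for (id in names(edges)) {
      v[as.character(edges[[id]][1L])] <- id
      v[as.character(edges[[id]][2L])] <- id
    }
    v
  }
  structure(list(vertices = sort(vertices), blue = blue, red = red,
                 vblue = vmap(blue), vred = vmap(red),
                 cycles_gained = 0L, closed = FALSE),
            class = "feg")
}

#' @export
print.feg <- function(x, ...) {
  cat("free-extremities graph:", length(x$vertices), "vertices,",
      length(x$blue), "blue +", length(x$red), "red edges,",
      feg_cycles(x), "cycle components\n")
  invisible(x)
}

#' Number of blue edges of a free-extremities graph
#' @param r an `feg` object.
#' @export
feg_n_blue <- function(r) length(r$blue)

# blue / red partner of a vertex
feg_partner <- function(r, v, color = c("blue", "red")) {
  color <- match.arg(color)
  map <- if (color == "blue") r$vblue else r$vred
  edges <- if (color == "blue") r$blue else r$red
  e <- edges[[map[[as.character(v)]]]]
  if (e[1L] == v) e[2L] else e[1L]
}

#' Cycle components of a free-extremities graph
#'
#' Components are traced by alternating blue and red perfect-matching
#' partners; every component is an even alternating cycle.
#'
#' @param r an `feg` object.
#' @param membership return the component id per vertex instead of the
#'   count.
#' @return integer count, or named integer vector when `membership`.
#' @export
feg_cycles <- function(r, membership = FALSE) {
  verts <- r$vertices
  comp <- stats::setNames(rep(NA_integer_, length(verts)),
                          as.character(verts))
  cid <- 0L
  for (v in verts) {
    if (!is.na(comp[[as.character(v)]])) next
    cid <- cid + 1L
    # leave v by its blue edge; the walk can only return to v by its red
    # edge, after traversing the whole (even, alternating) cycle
    cur <- v
    use_blue <- TRUE
    repeat {
      comp[[as.character(cur)]] <- cid
      nxt <- feg_partner(r, cur, if (use_blue) "blue" else "red")
      use_blue <- !use_blue
      if (nxt == v) break
      cur <- nxt
    }
  }
  if (membership) comp else cid
}

#' Record the effect of adding an adjacency on the free-extremities graph
#'
#' Removes `u` and `v` and identifies their incident blue edges (if they
#' are the same blue edge a breakpoint cycle is gained) and their incident
#' red edges. Identifying the same red edge closes a chromosome and is only
#' legal when `u` and `v` are the last two vertices.
#'
#' @param r an `feg` object.
#' @param u,v distinct vertices of `r` (codes or tokens).
#' @return the updated `feg`.
#' @export
feg_update <- function(r, u, v) {
  u <- ext(u); v <- ext(v)
  if (r$closed) stop("graph already closed")
  if (u == v || !(u %in% r$vertices) || !(v %in% r$vertices))
    stop("u and v must be distinct vertices of the graph")
  cu <- as.character(u); cv <- as.character(v)

  merge_color <- function(edges, vmap, same_action) {
    eu <- vmap[[cu]]; ev <- vmap[[cv]]
    if (eu == ev) {
      same_action()
      edges[[eu]] <- NULL
      vmap <- vmap[!names(vmap) %in% c(cu, cv)]
    } else {
      a <- setdiff(edges[[eu]], u)
      b <- setdiff(edges[[ev]], v)
      edges[[eu]] <- sort(c(a, b))
      edges[[ev]] <- NULL
      vmap <- vmap[!names(vmap) %in% c(cu, cv)]
      vmap[[as.character(a)]] <- eu
      vmap[[as.character(b)]] <- eu
    }
    list(edges = edges, vmap = vmap)
  }

  gained <- FALSE
  bl <- merge_color(r$blue, r$vblue, function() gained <<- TRUE)
  closing <- identical(r$vred[[cu]], r$vred[[cv]])
  if (closing && length(r$vertices) > 2L)
    stop("illegal update: joining the ends of the same open chromosome ",
         "while other free extremities remain would close a second ",
         "chromosome")
  rd <- merge_color(r$red, r$vred, function() NULL)

  r$vertices <- setdiff(r$vertices, c(u, v))
  r$blue <- bl$edges; r$vblue <- bl$vmap
  r$red <- rd$edges; r$vred <- rd$vmap
  if (gained) r$cycles_gained <- r$cycles_gained + 1L
  if (!length(r$vertices)) r$closed <- TRUE
  r
}

#' Maximum number of blue-edge updates
#'
#' The closed form `Nb(R) - c(R) + 1`: the number of blue edges minus the
#' number of cycle components plus one. This is the largest number of
#' update transformations that can use blue edges over all legal update
#' sequences, and therefore the maximum breakpoint-cycle gain of any
#' circular unichromosomal completion.
#'
#' @param r an `feg` object.
#' @return non-negative integer.
#' @export
max_blue_updates <- function(r) {
  stopifnot(inherits(r, "feg"))
  feg_n_blue(r) - feg_cycles(r) + 1L
}

#' Exhaustive search oracle for the blue-update maximum
#'
#' Tries every legal update sequence and returns the maximum number of
#' updates that used a current blue edge. Exponential; guarded; used to
#' validate [max_blue_updates()].
#'
#' @param r an `feg` object.
#' @param max_vertices guard (default 10).
#' @return non-negative integer.
#' @export
max_blue_updates_search <- function(r, max_vertices = 10L) {
  stopifnot(inherits(r, "feg"))
  if (length(r$vertices) > max_vertices)
    stop("graph too large for exhaustive update-sequence search")
  recurse <- function(r) {
    verts <- r$vertices
    if (!length(verts)) return(0L)
    best <- -1L
    pairs <- utils::combn(verts, 2L)
    for (i in seq_len(ncol(pairs))) {
      u <- pairs[1L, i]; v <- pairs[2L, i]
      same_red <- identical(r$vred[[as.character(u)]],
                            r$vred[[as.character(v)]])
      if (same_red && length(verts) > 2L) next
      is_blue <- identical(r$vblue[[as.character(u)]],
                           r$vblue[[as.character(v)]])
      sub <- recurse(feg_update(r, u, v))
      best <- max(best, as.integer(is_blue) + sub)
    }
    best
  }
  recurse(r)
}

# --- Algorithm for the circular unichromosomal completion -------------------

#' Optimal circular unichromosomal completion
#'
#' Exact greedy algorithm on the free-extremities graph: while more than
#' one cycle component remains, join the lexicographically smallest pair of
#' vertices from different cycles; then, while more than one blue edge
#' remains, add the smallest blue edge; finally add the single remaining
#' excluded (red) edge. Both pick rules are optimal adjacencies, so the
#' completion maximizes the breakpoint cycle count `c(., ref)` over all
#' circular unichromosomal completions of `g`.
#'
#' @param g a partial genome completable to circular unichromosomal form;
#'   if already complete it is returned unchanged.
#' @param ref the reference genome; must be circular.
#' @return a `genome` (circular unichromosomal) containing `g`, with
#'   attribute `cycles` giving `c(result, ref)`.
#' @examples
#' complete_circular(genome(1), genome(1, "1h 1t"))
#' @export
complete_circular <- function(g, ref) {
  stopifnot(inherits(g, "genome"), inherits(ref, "genome"))
  if (g$n_genes != ref$n_genes)
    stop("genomes must be on the same number of genes")
  if (length(telomeres(ref)))
    stop("reference must be circular")
  if (!is_completable(g, c("circular", "unichromosomal")))
    stop("partial genome is not completable to a circular unichromosomal ",
         "genome")
  if (!length(free_extremities(g))) {
    res <- g   # already a circular unichromosomal genome
  } else {
    r <- free_extremities_graph(g, ref)
    added <- matrix(integer(), ncol = 2L)
    pick_cross_cycle <- function(r) {
      comp <- feg_cycles(r, membership = TRUE)
      u <- r$vertices[1L]
      others <- r$vertices[comp[as.character(r$vertices)] !=
                             comp[[as.character(u)]]]
      c(u, min(others))
    }
    while (feg_cycles(r) > 1L) {
      uv <- pick_cross_cycle(r)
      added <- rbind(added, uv)
      r <- feg_update(r, uv[1L], uv[2L])
    }
    while (feg_n_blue(r) > 1L) {
      ends <- t(vapply(r$blue, identity, integer(2L)))
      pick <- order(ends[, 1L], ends[, 2L])[1L]
      uv <- ends[pick, ]
      added <- rbind(added, uv)
      r <- feg_update(r, uv[1L], uv[2L])
    }
    # single remaining excluded edge closes the chromosome
    last <- r$red[[1L]]
    added <- rbind(added, last)
    r <- feg_update(r, last[1L], last[2L])
    res <- genome(g$n_genes, rbind(g$adj, added))
  }
  structure(res, cycles = bg_counts(breakpoint_graph(list(res, ref)))[["cycles"]])
}

#' Cycle-membership correction term for linear references
#'
#' For a reference adjacency `e` of a circular unichromosomal reference,
#' `theta(e)` is 2 if `e` lies on a cycle component of the breakpoint graph
#' `B(G, ref)` and 1 otherwise. It is the gap between the best circular and
#' best linear unichromosomal completions when `e` is the adjacency removed
#' from the reference.
#'
#' @param g the partial genome.
#' @param ref circular unichromosomal reference genome.
#' @param e an adjacency of `ref` (any form accepted by [genome()]
#'   adjacency input, a single pair).
#' @return integer, 1 or 2.
#' @export
theta <- function(g, ref, e) {
  stopifnot(inherits(g, "genome"), inherits(ref, "genome"))
  e <- as_adj_matrix(e)
  if (nrow(e) != 1L) stop("e must be a single adjacency")
  if (!adj_key(e) %in% adj_strings(ref$adj))
    stop("e is not an adjacency of the reference")
  if (!satisfies(ref, c("circular", "unichromosomal")))
    stop("reference must be circular unichromosomal")
  bg <- breakpoint_graph(list(g, ref))
  cid <- bg$membership[e[1L, 1L]]
  kind <- bg$components$kind[bg$components$component == cid]
  if (kind == "cycle") 2L else 1L
}

#' Optimal linear unichromosomal completion
#'
#' Solves the linear unichromosomal case through the circular one: the
#' unique excluded edge `e` of the linear reference (joining its two
#' telomeres) is added to form a circular reference, [complete_circular()]
#' is run, and one added adjacency is removed — an added adjacency sharing
#' `e`'s breakpoint cycle when `theta(e) = 1`, otherwise the smallest added
#' adjacency. The result is linear unichromosomal, contains `g`, and
#' attains the maximum cycle count, which equals the circular optimum minus
#' `theta(e)`.
#'
#' @param g a partial genome completable to linear unichromosomal form; if
#'   already complete it is returned unchanged.
#' @param ref linear unichromosomal reference genome.
#' @return a `genome` with attributes `cycles` (`c(result, ref)`) and
#'   `theta`.
#' @export
complete_linear <- function(g, ref) {
  stopifnot(inherits(g, "genome"), inherits(ref, "genome"))
  if (g$n_genes != ref$n_genes)
    stop("genomes must be on the same number of genes")
  if (!satisfies(ref, c("linear", "unichromosomal")))
    stop("reference must be linear unichromosomal")
  if (!is_completable(g, c("linear", "unichromosomal")))
    stop("partial genome is not completable to a linear unichromosomal ",
         "genome")
  if (satisfies(g, c("linear", "unichromosomal")) &&
      nrow(g$adj) == g$n_genes - 1L) {
    res <- g
    return(structure(res,
      cycles = bg_counts(breakpoint_graph(list(res, ref)))[["cycles"]],
      theta = NA_integer_))
  }
  e <- sort(telomeres(ref))
  ref_c <- genome(ref$n_genes, rbind(ref$adj, e))
  gc <- complete_circular(g, ref_c)
  th <- theta(g, ref_c, matrix(e, ncol = 2L))
  added <- gc$adj[!adj_strings(gc$adj) %in% adj_strings(g$adj), ,
                  drop = FALSE]
  if (th == 1L) {
    bgc <- breakpoint_graph(list(gc, ref_c))
    ecomp <- bgc$membership[e[1L]]
    in_cycle <- bgc$membership[added[, 1L]] == ecomp
    cand <- added[in_cycle, , drop = FALSE]
    if (!nrow(cand))
      stop("internal error: no added adjacency shares the breakpoint ",
           "cycle of e although theta(e) = 1")
    f <- cand[1L, ]   # canonical order: smallest such edge
  } else {
    f <- added[1L, ]
  }
  keep <- gc$adj[adj_strings(gc$adj) != paste(ext_token(f[1L]),
                                              ext_token(f[2L])), ,
                 drop = FALSE]
  res <- genome(g$n_genes, keep)
  structure(res,
            cycles = bg_counts(breakpoint_graph(list(res, ref)))[["cycles"]],
            theta = th)
}
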