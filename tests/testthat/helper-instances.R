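# Seeded random instance generators and small independent oracles shared
# across the suite. Everything here is deliberately naive: the point is
# independence from the algorithms under test.

# random reference with a random feasible chromosome composition
rand_ref <- function(n) {
  k <- sample(1:n, 1)
  nc <- sample(0:k, 1)
  random_genome(n, k - nc, nc)
}

# random partial genome: scramble a random genome, drop adjacencies
rand_partial <- function(n, pmask = 0.5) {
  g <- scramble_genome(rand_ref(n), sample(0:2, 1))
  keep <- stats::runif(nrow(g$adj)) >= pmask
  genome(n, g$adj[keep, , drop = FALSE])
}

# every genome (matching over extremities) on n genes, by direct recursion
all_matchings <- function(n) {
  out <- list()
  rec <- function(rem, chosen) {
    if (!length(rem)) {
      out[[length(out) + 1L]] <<- genome(n, chosen)
      return(invisible(NULL))
    }
    u <- rem[1L]
    rest <- rem[-1L]
    rec(rest, chosen)
    for (v in rest) rec(setdiff(rest, v), rbind(chosen, c(u, v)))
  }
  rec(seq_len(2L * n), matrix(integer(), ncol = 2L))
  out
}

# naive chromatic-index decision: try all k^m color assignments
naive_colorable <- function(edges, k) {
  m <- nrow(edges)
  if (m == 0L) return(TRUE)
  grid <- expand.grid(rep(list(seq_len(k)), m))
  for (i in seq_len(nrow(grid))) {
    col <- as.integer(grid[i, ])
    ok <- TRUE
    for (cl in seq_len(k)) {
      vs <- as.vector(edges[col == cl, , drop = FALSE])
      if (anyDuplicated(vs)) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# maximum breakpoint-cycle count over a list of completions
best_cycles <- function(completions, ref) {
  max(vapply(completions, function(x)
    sum(breakpoint_graph(list(x, ref))$components$kind == "cycle"), 0L))
}

cycles_with <- function(g, ref)
  sum(breakpoint_graph(list(g, ref))$components$kind == "cycle")

genome_id <- function(g) format(g)
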