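# run expr with the RNG seeded, restoring the caller's RNG state after
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Random genome with a prescribed chromosome composition
#'
#' Draws a uniformly shuffled gene order and orientation and arranges it
#' into the requested numbers of linear and circular chromosomes (sizes
#' drawn uniformly among compositions with at least one gene each).
#' Deterministic given `seed`.
#'
#' @param n number of genes.
#' @param n_linear,n_circular chromosome counts; their sum must be between
#'   1 and `n`.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return a `genome`.
#' @examples
#' random_genome(5, n_linear = 0, n_circular = 1, seed = 1)
#' @export
random_genome <- function(n, n_linear = 1L, n_circular = 0L, seed = NULL) {
  n <- as.integer(n)
  kch <- n_linear + n_circular
  if (n < 1L || kch < 1L || kch > n)
    stop("infeasible chromosome spec: need 1 <= n_linear + n_circular <= n")
  with_seed(seed, {
    genes <- sample.int(n) * sample(c(1L, -1L), n, replace = TRUE)
    # composition of n into kch positive parts
    cuts <- if (kch > 1L) sort(sample.int(n - 1L, kch - 1L)) else integer()
    bounds <- c(0L, cuts, n)
    kinds <- sample(c(rep("$", n_linear), rep("@", n_circular)))
    chrom <- vapply(seq_len(kch), function(i) {
      paste(c(genes[(bounds[i] + 1L):bounds[i + 1L]], kinds[i]),
            collapse = " ")
    }, "")
    from_signed_permutations(chrom)
  })
}

#' Scramble a genome by random DCJ moves
#'
#' Applies `moves` uniformly chosen double-cut-and-join operations (each
#' drawn from the full neighbor set of the current genome). The DCJ
#' distance to the start is at most `moves`; for small `moves` and large
#' `n` random moves rarely cancel, so the distance usually equals `moves`.
#'
#' @param g a `genome`.
#' @param moves number of moves (>= 0).
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return a `genome`, with attribute `move_log` (canonical adjacency
#'   string of the genome after each move).
#' @export
scramble_genome <- function(g, moves, seed = NULL) {
  stopifnot(inherits(g, "genome"), moves >= 0L)
  with_seed(seed, {
    log <- character()
    for (i in seq_len(moves)) {
      nb <- dcj_neighbors(g)
      g <- nb[[sample.int(length(nb), 1L)]]
      log <- c(log, genome_key(g))
    }
    structure(g, move_log = log)
  })
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of a synthetic mixture: reference
#' size and chromosome composition, the true mixture tree, the number of
#' DCJ moves along each tree edge, the per-adjacency masking probability,
#' and the seed all randomness flows from.
#'
#' @param n_genes reference size.
#' @param n_linear,n_circular reference chromosome counts.
#' @param parents parent list of the true mixture tree over the `k`
#'   genomes (0 = reference); see [mixture_tree()].
#' @param moves integer vector (length `k` or 1, recycled): DCJ moves on
#'   the tree edge above each genome.
#' @param mask per-adjacency masking probability in `[0, 1]` (recycled to
#'   length `k`).
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes, n_linear = 1L, n_circular = 0L,
                       parents = 0L, moves = 2L, mask = 0.2, seed = 1L) {
  tree <- mixture_tree(parents)
  k <- tree$k
  if (any(tree$parents >= seq_len(k)))
    stop("parents[i] must be an earlier genome (or 0): topological order")
  moves <- rep_len(as.integer(moves), k)
  mask <- rep_len(as.numeric(mask), k)
  if (any(moves < 0L)) stop("moves must be non-negative")
  if (any(mask < 0 | mask > 1)) stop("mask must be in [0, 1]")
  structure(list(n_genes = as.integer(n_genes), n_linear = as.integer(n_linear),
                 n_circular = as.integer(n_circular), tree = tree,
                 moves = moves, mask = mask, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a partial multi-genome mixture with ground truth
#'
#' Generates a reference genome, derives the `k` true genomes by scrambling
#' along the configured mixture tree, masks each genome's adjacencies
#' independently (per-adjacency Bernoulli dropout), and pools the retained
#' adjacencies into an unattributed multiset. Identical configurations
#' yield identical instances.
#'
#' @param config a [sim_config()].
#' @return object of class `mcp_simulation`: list with `reference`,
#'   `genomes` (the true genomes), `tree`, `observed` (list of masked
#'   partial genomes), `mixture` (a `multi_genome`), `attribution`
#'   (genome of origin for each mixture adjacency row) and `config`.
#' @export
simulate_mixture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ref <- random_genome(config$n_genes, config$n_linear, config$n_circular)
    k <- config$tree$k
    genomes <- vector("list", k)
    for (i in seq_len(k)) {
      parent <- if (config$tree$parents[i] == 0L) ref
        else genomes[[config$tree$parents[i]]]
      genomes[[i]] <- scramble_genome(parent, config$moves[i])
    }
    observed <- vector("list", k)
    mix_rows <- matrix(integer(), ncol = 2L)
    attribution <- integer()
    for (i in seq_len(k)) {
      adj <- genomes[[i]]$adj
      keep <- if (nrow(adj)) stats::runif(nrow(adj)) >= config$mask[i]
        else logical()
      observed[[i]] <- genome(config$n_genes, adj[keep, , drop = FALSE])
      mix_rows <- rbind(mix_rows, adj[keep, , drop = FALSE])
      attribution <- c(attribution, rep(i, sum(keep)))
    }
    ord <- order(mix_rows[, 1L], mix_rows[, 2L])
    structure(list(reference = ref, genomes = genomes, tree = config$tree,
                   observed = observed,
                   mixture = multi_genome(config$n_genes,
                                          mix_rows[ord, , drop = FALSE]),
                   attribution = attribution[ord], config = config),
              class = "mcp_simulation")
  })
}

#' @export
print.mcp_simulation <- function(x, ...) {
  cat("simulated mixture:", x$tree$k, "genomes on", x$config$n_genes,
      "genes;", nrow(x$mixture$adj), "observed adjacencies\n")
  invisible(x)
}
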