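#' Expand a 3-literal clause into conjunctions
#'
#' Rewrites one disjunctive clause over three distinct variables into the
#' seven 3-literal conjunctions obtained by flipping literal signs in all
#' ways except negating all three. For every truth assignment at most one
#' of the seven is satisfied, and exactly one is satisfied precisely when
#' the clause is: applied clause-by-clause, this turns maximum clause
#' satisfaction into maximum conjunction satisfaction.
#'
#' @param clause integer vector of three non-zero literals (DIMACS
#'   convention: sign = polarity, absolute value = variable), distinct
#'   variables.
#' @return list of 7 integer vectors (conjunctions).
#' @examples
#' length(expand_clause(c(1, 2, 3)))  # 7
#' @export
expand_clause <- function(clause) {
  clause <- as.integer(clause)
  if (length(clause) != 3L || any(clause == 0L))
    stop("clause must consist of exactly 3 non-zero literals")
  if (anyDuplicated(abs(clause)))
    stop("clause variables must be distinct")
  signs <- as.matrix(expand.grid(c(1L, -1L), c(1L, -1L), c(1L, -1L)))
  keep <- rowSums(signs) != -3L   # drop the all-negated pattern
  lapply(which(keep), function(i) signs[i, ] * clause)
}

# satisfied_conjunction: all literals true under named logical assignment
conj_satisfied <- function(conj, assignment) {
  vals <- assignment[as.character(abs(conj))]
  if (any(is.na(vals))) stop("assignment misses variable(s): ",
                             paste(abs(conj)[is.na(vals)], collapse = " "))
  all(ifelse(conj > 0L, vals, !vals))
}

#' Hardness gadget: a mixture instance encoding conjunction satisfaction
#'
#' Builds the constructive reduction from maximum 3-conjunction
#' satisfaction to the 2-genome mixture completion problem. Every variable
#' becomes an even cycle (length `4t` for a variable whose literals appear
#' `t` times, minimum 4) whose two perfect matchings encode true and
#' false. Every 3-literal conjunction becomes a 6-cycle: one host edge per
#' literal, drawn from the variable's true matching for a positive literal
#' and false matching for a negative one, linked by three new conjunction
#' edges. Host edges are spaced so that no variable-cycle edge touches
#' conjunction edges of two different conjunction-cycles. `3m + 1`
#' single-variable padding conjunctions (`m` = number of input
#' conjunctions) are added on fresh variables, forcing the optimal mixture
#' tree into path shape. All variable-cycle edges form the partial
#' multi-genome `M`; the conjunction edges form the reference genome `A`.
#'
#' @param conjunctions list of integer literal vectors, each of length 3
#'   (distinct variables) or length 1; 2-literal conjunctions are not
#'   supported.
#' @return object of class `mcp_gadget`: list with `mixture` (a
#'   `multi_genome`), `reference` (a `genome`), `variables` (per-variable
#'   cycle bookkeeping: `vertices`, `true_matching`, `false_matching`),
#'   `conjunctions` (input conjunctions with their host and conjunction
#'   edges), `padding` (the padding conjunctions), `n_genes`.
#' @examples
#' gad <- build_gadget(list(c(-1, -2, 3)))
#' nrow(gad$reference$adj)  # 3 conjunction edges
#' @export
build_gadget <- function(conjunctions = list()) {
  conjunctions <- lapply(conjunctions, as.integer)
  sizes <- lengths(conjunctions)
  if (any(!sizes %in% c(1L, 3L)))
    stop("conjunctions must have 1 or 3 literals")
  if (any(vapply(conjunctions, function(cj) any(cj == 0L) ||
                   anyDuplicated(abs(cj)) > 0L, TRUE)))
    stop("conjunction literals must be non-zero over distinct variables")
  m <- length(conjunctions)
  input_vars <- sort(unique(unlist(lapply(conjunctions, abs))))
  pad_vars <- max(c(0L, input_vars)) + seq_len(3L * m + 1L)
  padding <- lapply(pad_vars, function(v) v)   # single positive literal
  vars <- c(input_vars, pad_vars)

  # t(x): appearances of x's literals among 3-literal conjunctions
  t_count <- stats::setNames(rep(0L, length(vars)), vars)
  for (cj in conjunctions) if (length(cj) == 3L)
    for (lit in cj) t_count[[as.character(abs(lit))]] <-
      t_count[[as.character(abs(lit))]] + 1L

  variables <- list()
  offset <- 0L
  for (v in vars) {
    len <- 4L * max(t_count[[as.character(v)]], 1L)   # even, >= 4t
    verts <- offset + seq_len(len)
    nxt <- c(verts[-1L], verts[1L])
    edge_at <- function(p) sort(c(verts[p], nxt[p]))  # edge position p
    all_pos <- seq_len(len)
    variables[[as.character(v)]] <- list(
      vertices = verts,
      edges = t(vapply(all_pos, edge_at, integer(2L))),
      true_matching = t(vapply(all_pos[all_pos %% 2L == 1L], edge_at,
                               integer(2L))),
      false_matching = t(vapply(all_pos[all_pos %% 2L == 0L], edge_at,
                                integer(2L))),
      next_slot = 1L)
    offset <- offset + len
  }
  n_genes <- offset %/% 2L

  conj_records <- list()
  ref_edges <- matrix(integer(), ncol = 2L)
  for (ci in seq_along(conjunctions)) {
    cj <- conjunctions[[ci]]
    if (length(cj) == 1L) {
      conj_records[[ci]] <- list(literals = cj, hosts = NULL,
                                 conj_edges = NULL)
      next
    }
    hosts <- matrix(integer(), ncol = 2L)
    for (lit in cj) {
      vb <- variables[[as.character(abs(lit))]]
      slot <- vb$next_slot
      # appearance j hosts on edge position 4(j-1)+1 (true side) or
      # 4(j-1)+2 (false side): hosts of different appearances are >= 3
      # edge positions apart, so no cycle edge touches two conjunction
      # cycles
      # matchings hold the edges at odd (true) / even (false) positions in
      # position order; appearance j uses the edge at position 4(j-1)+1 or
      # 4(j-1)+2, i.e. the (2j-1)-th edge of the respective matching
      mat <- if (lit > 0L) vb$true_matching else vb$false_matching
      hosts <- rbind(hosts, mat[2L * slot - 1L, ])
      variables[[as.character(abs(lit))]]$next_slot <- slot + 1L
    }
    # link host edges h1={a1,b1}, h2={a2,b2}, h3={a3,b3} into a 6-cycle
    ce <- rbind(c(hosts[1L, 2L], hosts[2L, 1L]),
                c(hosts[2L, 2L], hosts[3L, 1L]),
                c(hosts[3L, 2L], hosts[1L, 1L]))
    conj_records[[ci]] <- list(literals = cj, hosts = hosts,
                               conj_edges = ce)
    ref_edges <- rbind(ref_edges, ce)
  }

  mix_edges <- do.call(rbind, lapply(variables, `[[`, "edges"))
  structure(list(
    mixture = multi_genome(n_genes, mix_edges),
    reference = genome(n_genes, ref_edges),
    variables = lapply(variables, function(vb)
      vb[c("vertices", "edges", "true_matching", "false_matching")]),
    conjunctions = conj_records,
    padding = padding,
    n_genes = n_genes), class = "mcp_gadget")
}

#' @export
print.mcp_gadget <- function(x, ...) {
  cat("mixture-hardness gadget:", length(x$variables), "variable-cycles (",
      length(x$padding), "padding ),", length(x$conjunctions),
      "input conjunctions,", x$n_genes, "genes\n")
  invisible(x)
}

#' Score of a truth assignment on a gadget instance
#'
#' Number of satisfied conjunctions — input conjunctions plus the padding
#' conjunctions (each satisfied when its variable is true). For 3-literal
#' conjunctions this equals the number of conjunction-cycles whose three
#' host edges all survive the matching choice of
#' [assignment_genome()].
#'
#' @param gadget an `mcp_gadget`.
#' @param assignment named logical vector over all gadget variables
#'   (input and padding), names = variable ids.
#' @return non-negative integer.
#' @export
assignment_score <- function(gadget, assignment) {
  stopifnot(inherits(gadget, "mcp_gadget"))
  input <- sum(vapply(gadget$conjunctions, function(cr)
    conj_satisfied(cr$literals, assignment), TRUE))
  pad <- sum(vapply(gadget$padding, conj_satisfied, TRUE,
                    assignment = assignment))
  as.integer(input + pad)
}

#' Genome induced by a truth assignment
#'
#' Chooses, in every variable-cycle, the true matching when the variable
#' is assigned true and the false matching otherwise; the union over
#' cycles is a perfect matching on the gadget extremities, i.e. a circular
#' genome.
#'
#' @inheritParams assignment_score
#' @return a `genome`.
#' @export
assignment_genome <- function(gadget, assignment) {
  stopifnot(inherits(gadget, "mcp_gadget"))
  rows <- lapply(names(gadget$variables), function(v) {
    val <- assignment[[v]]
    if (is.null(val) || is.na(val)) stop("assignment misses variable ", v)
    vb <- gadget$variables[[v]]
    if (val) vb$true_matching else vb$false_matching
  })
  genome(gadget$n_genes, do.call(rbind, rows))
}

#' Conjunction-cycles preserved by a truth assignment
#'
#' Counts the 3-literal conjunction-cycles all of whose host edges belong
#' to the matchings selected by the assignment.
#'
#' @inheritParams assignment_score
#' @return non-negative integer.
#' @export
preserved_conjunction_cycles <- function(gadget, assignment) {
  kept <- adj_strings(assignment_genome(gadget, assignment)$adj)
  sum(vapply(gadget$conjunctions, function(cr) {
    if (is.null(cr$hosts)) return(FALSE)
    all(adj_strings(canon_adj(cr$hosts)) %in% kept)
  }, TRUE))
}

#' Truth assignment induced by a genome on a gadget
#'
#' Inverse of [assignment_genome()]: for each variable-cycle, reports true
#' if the genome contains that cycle's true matching, false if the false
#' matching; errors if neither matching is fully contained.
#'
#' @param gadget an `mcp_gadget`.
#' @param g a `genome` on the gadget's genes.
#' @return named logical vector over the gadget variables.
#' @export
induced_assignment <- function(gadget, g) {
  stopifnot(inherits(gadget, "mcp_gadget"), inherits(g, "genome"))
  have <- adj_strings(g$adj)
  vals <- vapply(gadget$variables, function(vb) {
    if (all(adj_strings(canon_adj(vb$true_matching)) %in% have)) return(TRUE)
    if (all(adj_strings(canon_adj(vb$false_matching)) %in% have))
      return(FALSE)
    stop("genome selects neither matching of a variable-cycle")
  }, TRUE)
  names(vals) <- names(gadget$variables)
  vals
}

#' Exhaustive optimum of a conjunction-satisfaction instance
#'
#' Maximum [assignment_score()] over all `2^v` truth assignments; guarded.
#'
#' @param gadget an `mcp_gadget`.
#' @param max_vars guard (default 12).
#' @return list with `score` and one optimal `assignment`.
#' @export
max_3and_optimum <- function(gadget, max_vars = 12L) {
  vars <- names(gadget$variables)
  if (length(vars) > max_vars)
    stop("too many variables for exhaustive assignment search")
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(vars)))
  best <- -1L
  best_a <- NULL
  for (i in seq_len(nrow(grid))) {
    a <- stats::setNames(as.logical(grid[i, ]), vars)
    s <- assignment_score(gadget, a)
    if (s > best) {
      best <- s
      best_a <- a
    }
  }
  list(score = best, assignment = best_a)
}
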