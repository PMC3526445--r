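eval_clause <- function(clause, assignment) {
  vals <- assignment[as.character(abs(clause))]
  any(ifelse(clause > 0L, vals, !vals))
}

eval_conj <- function(conj, assignment) {
  vals <- assignment[as.character(abs(conj))]
  all(ifelse(conj > 0L, vals, !vals))
}

test_that("clause expansion yields 7 conjunctions with the selection
           property", {
  cj <- expand_clause(c(1L, 2L, 3L))
  expect_length(cj, 7L)
  expect_error(expand_clause(c(1L, 1L, 2L)), "distinct")
  expect_error(expand_clause(c(1L, 2L)), "exactly 3")
  # over all 8 assignments: number satisfied is 1 iff clause satisfied
  grid <- expand.grid(x = c(TRUE, FALSE), y = c(TRUE, FALSE),
                      z = c(TRUE, FALSE))
  for (clause in list(c(1L, 2L, 3L), c(-1L, 2L, -3L), c(-1L, -2L, -3L))) {
    cjs <- expand_clause(clause)
    for (i in seq_len(nrow(grid))) {
      a <- stats::setNames(as.logical(grid[i, ]), c("1", "2", "3"))
      nsat <- sum(vapply(cjs, eval_conj, TRUE, assignment = a))
      expect_equal(nsat, as.integer(eval_clause(clause, a)))
    }
  }
})

test_that("clause expansion preserves the satisfaction optimum", {
  # exhaustive instances on <= 3 variables
  set.seed(51)
  clauses_pool <- list(c(1L, 2L, 3L), c(-1L, 2L, 3L), c(1L, -2L, -3L),
                       c(-1L, -2L, -3L))
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), 3L))
  for (trial in 1:10) {
    inst <- sample(clauses_pool, sample(1:3, 1), replace = TRUE)
    conj <- unlist(lapply(inst, expand_clause), recursive = FALSE)
    best_sat <- best_and <- 0L
    for (i in seq_len(nrow(grid))) {
      a <- stats::setNames(as.logical(grid[i, ]), c("1", "2", "3"))
      best_sat <- max(best_sat,
                      sum(vapply(inst, eval_clause, TRUE, assignment = a)))
      best_and <- max(best_and,
                      sum(vapply(conj, eval_conj, TRUE, assignment = a)))
    }
    expect_equal(best_and, best_sat)
  }
})

test_that("gadget geometry: 6-cycles, padding count, even mixture cycles,
           host-edge separation", {
  for (conjs in list(list(),
                     list(c(-1L, -2L, 3L)),
                     list(c(1L, 2L, 3L), c(-1L, 2L, -4L)),
                     list(c(1L, 2L, 3L), c(1L, 2L, 3L), c(-1L, -2L, -3L)))) {
    gad <- build_gadget(conjs)
    m <- length(conjs)
    expect_length(gad$padding, 3L * m + 1L)
    expect_equal(nrow(gad$reference$adj), 3L * m)   # conjunction edges
    # reference is a genome (matching) by construction
    expect_s3_class(gad$reference, "genome")
    # every conjunction-cycle has exactly 6 edges forming one cycle
    for (cr in gad$conjunctions) {
      six <- rbind(cr$hosts, cr$conj_edges)
      expect_equal(nrow(six), 6L)
      deg <- table(as.vector(six))
      expect_true(all(deg == 2L))
      expect_length(deg, 6L)
    }
    # mixture graph is a disjoint union of even cycles
    gg <- genome_graph(gad$mixture)
    expect_true(all(gg$degree == 2L))
    for (vb in gad$variables) {
      expect_equal(length(vb$vertices) %% 4L, 0L)
      expect_gte(length(vb$vertices), 4L)
    }
    # no variable-cycle edge touches conjunction edges from two different
    # conjunction-cycles
    owner <- list()
    for (ci in seq_along(gad$conjunctions)) {
      ce <- gad$conjunctions[[ci]]$conj_edges
      if (is.null(ce)) next
      for (v in as.vector(ce))
        owner[[as.character(v)]] <- c(owner[[as.character(v)]], ci)
    }
    for (vb in gad$variables) for (r in seq_len(nrow(vb$edges))) {
      tied <- unique(unlist(owner[as.character(vb$edges[r, ])]))
      expect_lte(length(tied), 1L)
    }
    # untouched-cycle bookkeeping: 3m+1 padding cycles vs 3m ref edges
    touched <- unique(unlist(lapply(gad$conjunctions, function(cr)
      if (is.null(cr$hosts)) NULL
      else ext_gene(as.vector(cr$hosts)))))
    untouched <- sum(vapply(gad$variables, function(vb)
      !any(ext_gene(vb$vertices) %in% touched), TRUE))
    expect_gte(untouched, 3L * m + 1L)
  }
  expect_error(build_gadget(list(c(1L, 2L))), "1 or 3")
})

test_that("assignment scoring matches conjunction-cycle preservation", {
  gad <- build_gadget(list(c(-1L, -2L, 3L)))
  vars <- names(gad$variables)
  # x = y = FALSE, z = TRUE satisfies the conjunction; padding all true
  a <- stats::setNames(c(FALSE, FALSE, TRUE, rep(TRUE, 4L)), vars)
  expect_equal(assignment_score(gad, a), 5L)   # 1 + (3m+1) padding
  expect_equal(preserved_conjunction_cycles(gad, a), 1L)
  a2 <- a; a2[["1"]] <- TRUE                   # flipping x destroys the cycle
  expect_equal(assignment_score(gad, a2), 4L)
  expect_equal(preserved_conjunction_cycles(gad, a2), 0L)

  # equivalence on random assignments for a larger instance
  gad2 <- build_gadget(list(c(1L, 2L, 3L), c(-1L, 2L, -4L)))
  vars2 <- names(gad2$variables)
  set.seed(52)
  for (i in 1:20) {
    a <- stats::setNames(sample(c(TRUE, FALSE), length(vars2),
                                replace = TRUE), vars2)
    n3sat <- sum(vapply(gad2$conjunctions, function(cr)
      eval_conj(cr$literals, a), TRUE))
    expect_equal(preserved_conjunction_cycles(gad2, a), n3sat)
    g <- assignment_genome(gad2, a)
    expect_equal(length(telomeres(g)), 0L)     # perfect matching
    expect_identical(unname(induced_assignment(gad2, g)[vars2]), unname(a))
  }
  expect_error(assignment_score(gad, a[-1L]), "misses")
})

test_that("the 2-genome optimum of a tiny gadget recovers the
           conjunction-satisfaction optimum via a path tree", {
  for (conjs in list(list(), list(c(-1L, -2L, 3L)))) {
    gad <- build_gadget(conjs)
    sol <- brute_force_kmcp(gad$mixture, gad$reference, 2,
                            max_n = gad$n_genes)
    expect_true(sol$valid)
    # optimal tree is a path tree (exactly one genome hangs off the root)
    expect_equal(sum(sol$tree$parents == 0L), 1L)
    mid <- which(sol$tree$parents == 0L)
    ind <- induced_assignment(gad, sol$genomes[[mid]])
    # padding cycles carry no reference edges, so the mixture objective is
    # indifferent to them; any optimal assignment sets them true
    ind[as.character(unlist(gad$padding))] <- TRUE
    expect_equal(assignment_score(gad, ind), max_3and_optimum(gad)$score)
  }
})

test_that("a mixture of untouched even cycles forces the path tree", {
  # 4 even cycles, reference with 1 edge: 3 untouched cycles > 2 * 1 edge
  cyc <- function(genes) {
    v <- as.vector(rbind(2L * genes - 1L, 2L * genes))
    cbind(v, c(v[-1L], v[1L]))
  }
  m <- multi_genome(8, do.call(rbind, lapply(list(1:2, 3:4, 5:6, 7:8), cyc)))
  a <- genome(8, matrix(c(ext("1t"), ext("2t")), ncol = 2))
  sol <- brute_force_kmcp(m, a, 2, max_n = 8)
  expect_true(sol$valid)
  expect_equal(sum(sol$tree$parents == 0L), 1L)
})
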