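# shared micro-instance: genes 1..3, G = {{1h,2t}},
# circular reference A = {{1h,2t},{2h,3t},{3h,1t}}
micro_G <- function() genome(3, "1h 2t")
micro_A <- function() genome(3, c("1h 2t", "2h 3t", "3h 1t"))

feg_edge_set <- function(edges)
  sort(vapply(edges, function(e) paste(ext_token(e), collapse = "-"), ""))

test_that("free-extremities graph pairs path endpoints as two matchings", {
  r1 <- free_extremities_graph(genome(1), genome(1, "1h 1t"))
  expect_equal(length(r1$vertices), 2L)
  expect_equal(feg_n_blue(r1), 1L)
  expect_equal(feg_cycles(r1), 1L)

  r <- free_extremities_graph(micro_G(), micro_A())
  expect_equal(ext_token(r$vertices), c("1t", "2h", "3t", "3h"))
  expect_setequal(feg_edge_set(r$blue), c("2h-3t", "1t-3h"))
  expect_setequal(feg_edge_set(r$red), c("1t-2h", "3t-3h"))

  expect_error(free_extremities_graph(genome(2), genome(2, "1h 2t")),
               "circular")
  expect_error(free_extremities_graph(genome(1, "1h 1t"),
                                      genome(1, "1h 1t")),
               "no free extremities")
})

test_that("free-extremities graphs satisfy the matching-size identity and
           consist of even alternating cycles", {
  set.seed(21)
  checked <- 0L
  while (checked < 40L) {
    n <- sample(1:5, 1)
    ref <- random_genome(n, 0, sample(1:n, 1))
    g <- rand_partial(n)
    if (!is_completable(g, c("circular", "unichromosomal")) ||
        !length(free_extremities(g))) next
    checked <- checked + 1L
    r <- free_extremities_graph(g, ref)
    expect_equal(length(r$blue), length(r$red))
    expect_equal(2L * length(r$blue), length(r$vertices))
    # each color is a perfect matching on the vertices
    for (col in c("blue", "red")) {
      ends <- sort(unname(unlist(r[[col]])))
      expect_equal(ends, sort(r$vertices))
    }
    # alternating components close into even cycles
    memb <- feg_cycles(r, membership = TRUE)
    expect_false(anyNA(memb))
    expect_true(all(table(memb) %% 2L == 0L))
  }
})

test_that("update removes the pair and merges or closes edges", {
  r1 <- free_extremities_graph(genome(1), genome(1, "1h 1t"))
  r1u <- feg_update(r1, "1t", "1h")
  expect_true(r1u$closed)
  expect_equal(r1u$cycles_gained, 1L)

  # updating across two cycles decreases the cycle count by one
  set.seed(22)
  found <- 0L
  while (found < 10L) {
    n <- sample(2:5, 1)
    ref <- random_genome(n, 0, 1)
    g <- rand_partial(n)
    if (!is_completable(g, c("circular", "unichromosomal")) ||
        !length(free_extremities(g))) next
    r <- free_extremities_graph(g, ref)
    if (feg_cycles(r) < 2L) next
    found <- found + 1L
    memb <- feg_cycles(r, membership = TRUE)
    u <- r$vertices[1L]
    v <- r$vertices[memb[as.character(r$vertices)] !=
                      memb[[as.character(u)]]][1L]
    expect_equal(feg_cycles(feg_update(r, u, v)), feg_cycles(r) - 1L)
  }

  # closing a chromosome early is rejected
  g <- genome(2)
  ref <- random_genome(2, 0, 1)
  r <- free_extremities_graph(g, ref)
  same_red <- r$red[[1L]]
  expect_error(feg_update(r, same_red[1L], same_red[2L]), "illegal")
})

test_that("blue-update maximum formula equals exhaustive sequence search", {
  r1 <- free_extremities_graph(genome(1), genome(1, "1h 1t"))
  expect_equal(max_blue_updates(r1), 1L)
  expect_equal(max_blue_updates_search(r1), 1L)
  set.seed(23)
  checked <- 0L
  while (checked < 40L) {
    n <- sample(1:4, 1)
    ref <- random_genome(n, 0, sample(1:n, 1))
    g <- rand_partial(n)
    if (!is_completable(g, c("circular", "unichromosomal")) ||
        !length(free_extremities(g))) next
    checked <- checked + 1L
    r <- free_extremities_graph(g, ref)
    expect_equal(max_blue_updates(r), max_blue_updates_search(r),
                 label = paste(genome_id(g), "ref", genome_id(ref)))
  }
})

test_that("unrestricted completion attains the oracle minimum distance", {
  expect_identical(format(complete_unrestricted(genome(1),
                                                genome(1, "1h 1t"))),
                   format(genome(1, "1h 1t")))
  # a complete genome is returned unchanged
  g <- random_genome(4, 1, 1, seed = 2)
  expect_identical(format(complete_unrestricted(g, g)), format(g))
  set.seed(24)
  for (i in 1:100) {
    n <- sample(1:3, 1)
    ref <- rand_ref(n)
    g <- rand_partial(n)
    out <- complete_unrestricted(g, ref)
    expect_true(all(adj_strings(g$adj) %in% adj_strings(out$adj)))
    opt <- min(vapply(enumerate_completions(g, character()),
                      dcj_distance, 0L, g2 = ref))
    expect_equal(dcj_distance(out, ref), opt,
                 label = paste(genome_id(g), "ref", genome_id(ref)))
  }
})

test_that("circular completion maximizes breakpoint cycles (oracle check)", {
  out1 <- complete_circular(genome(1), genome(1, "1h 1t"))
  expect_identical(format(out1), format(genome(1, "1h 1t")))
  expect_equal(attr(out1, "cycles"), 1L)
  expect_equal(dcj_distance(out1, genome(1, "1h 1t")), 0L)

  out3 <- complete_circular(micro_G(), micro_A())
  expect_equal(attr(out3, "cycles"), 3L)

  set.seed(25)
  checked <- 0L
  while (checked < 100L) {
    n <- sample(1:4, 1)
    ref <- random_genome(n, 0, sample(1:n, 1))
    g <- rand_partial(n)
    if (!is_completable(g, c("circular", "unichromosomal"))) next
    checked <- checked + 1L
    out <- complete_circular(g, ref)
    expect_true(satisfies(out, c("circular", "unichromosomal")))
    expect_true(all(adj_strings(g$adj) %in% adj_strings(out$adj)))
    opt <- best_cycles(
      enumerate_completions(g, c("circular", "unichromosomal")), ref)
    expect_equal(attr(out, "cycles"), opt,
                 label = paste(genome_id(g), "ref", genome_id(ref)))
  }
  expect_error(complete_circular(genome(2, "1h 1t"), random_genome(2, 0, 1)),
               "not completable")
})

test_that("theta reflects cycle membership of the reference adjacency", {
  expect_equal(theta(micro_G(), micro_A(), "2h 3t"), 1L)  # path component
  expect_equal(theta(micro_G(), micro_A(), "1h 2t"), 2L)  # doubled-edge cycle
  expect_equal(theta(genome(3), micro_A(), "1h 2t"), 1L)  # empty G: no cycles
  expect_error(theta(micro_G(), micro_A(), "1t 2h"), "not an adjacency")
})

test_that("linear completion attains the circular optimum minus theta", {
  # e = {1h,2t} sits on a cycle of B(G, Ac): theta = 2, cycles 3 - 2 = 1
  out1 <- complete_linear(micro_G(), genome(3, c("2h 3t", "3h 1t")))
  expect_equal(attr(out1, "cycles"), 1L)
  expect_equal(attr(out1, "theta"), 2L)
  # e = {2h,3t} on a path: theta = 1, cycles 3 - 1 = 2
  out2 <- complete_linear(micro_G(), genome(3, c("1h 2t", "3h 1t")))
  expect_equal(attr(out2, "cycles"), 2L)
  expect_equal(attr(out2, "theta"), 1L)
  # already-complete input comes back unchanged
  al <- random_genome(4, 1, 0, seed = 3)
  expect_identical(format(complete_linear(al, al)), format(al))

  set.seed(26)
  checked <- 0L
  while (checked < 60L) {
    n <- sample(2:4, 1)
    ac <- random_genome(n, 0, 1)
    e <- ac$adj[sample(nrow(ac$adj), 1L), , drop = FALSE]
    al <- genome(n, ac$adj[adj_strings(ac$adj) != adj_key(e), ,
                           drop = FALSE])
    g <- rand_partial(n)
    if (!is_completable(g, c("linear", "unichromosomal"))) next
    checked <- checked + 1L
    out <- complete_linear(g, al)
    expect_true(satisfies(out, c("linear", "unichromosomal")))
    expect_true(all(adj_strings(g$adj) %in% adj_strings(out$adj)))
    opt_l <- best_cycles(
      enumerate_completions(g, c("linear", "unichromosomal")), al)
    opt_c <- best_cycles(
      enumerate_completions(g, c("circular", "unichromosomal")), ac)
    expect_equal(attr(out, "cycles"), opt_l)
    expect_equal(opt_c, opt_l + theta(g, ac, e),
                 label = paste(genome_id(g), "ref", genome_id(al)))
  }
  expect_error(complete_linear(genome(2, "1h 1t"),
                               random_genome(2, 1, 0)),
               "not completable")
})

test_that("solvers handle instances far beyond the oracle range", {
  # growing-chain smoke test of the linear-time claims (structure only)
  for (n in c(50L, 200L)) {
    ref <- random_genome(n, 0, 1, seed = n)
    g <- genome(n, ref$adj[seq_len(n %/% 2L), , drop = FALSE])
    out <- complete_circular(g, ref)
    expect_true(satisfies(out, c("circular", "unichromosomal")))
    # the only cycle-count-n completion of a sub-matching of a circular
    # unichromosomal reference is the reference itself
    expect_equal(attr(out, "cycles"), n)
    expect_identical(format(out), format(ref))
    un <- complete_unrestricted(g, ref)
    expect_equal(dcj_distance(un, ref), 0L)
  }
})
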