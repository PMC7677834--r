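test_that("candidate cost reproduces hand values under the ordered-pair convention", {
  w <- two_triangle_world(lambda = 1)
  # two perfect triangles: density 2 each; homology 6 (ordered) over 6 proteins
  expect_equal(complex_cost(w$candidate), -5)

  # lambda scales only the homology term
  w10 <- two_triangle_world(lambda = 10)
  expect_equal(complex_cost(w10$candidate), -(2 + 2 + 10 * 1))

  # empty selection costs zero
  expect_equal(complex_cost(w$candidate, rep(FALSE, 6)), 0)

  # lambda = 0, single edgeless protein per network
  n1 <- ppi_network(matrix(character(), ncol = 2), "s1", proteins = "a1")
  n2 <- ppi_network(matrix(character(), ncol = 2), "s2", proteins = "a2")
  coll <- network_collection(list(n1, n2))
  sim <- similarity_map(list(), coll)
  cand <- complex_candidate(coll, sim, list("a1", "a2"), lambda = 0)
  expect_equal(complex_cost(cand), 0)
})

test_that("greedy pruning keeps clean complexes and removes pendants", {
  w <- two_triangle_world(lambda = 1)
  cx <- greedy_prune(w$candidate, trace = TRUE)
  expect_identical(cx$sets, list(c("a1", "b1", "c1"), c("a2", "b2", "c2")))
  expect_equal(cx$cost, -5)
  expect_equal(attr(cx, "trace"), -5)

  # pendant protein attached by one edge, no homolog: removed first, then stop
  n1 <- ppi_network(rbind(c("a1", "b1"), c("a1", "c1"), c("b1", "c1"),
                          c("c1", "x1")), "s1")
  n2 <- triangle_net(c("a2", "b2", "c2"), "s2")
  coll <- network_collection(list(n1, n2))
  tab <- data.frame(p = c("a1", "b1", "c1"), q = c("a2", "b2", "c2"), score = 1)
  sim <- similarity_map(list(list(net_i = 1, net_j = 2, table = tab)), coll)
  cand <- complex_candidate(coll, sim, list(c("a1", "b1", "c1", "x1"),
                                            c("a2", "b2", "c2")), lambda = 1)
  cx2 <- greedy_prune(cand, trace = TRUE)
  expect_identical(cx2$sets, list(c("a1", "b1", "c1"), c("a2", "b2", "c2")))
  tr <- attr(cx2, "trace")
  expect_equal(length(tr), 2L)  # exactly one removal
  expect_true(all(diff(tr) < 0))  # strictly decreasing
})

test_that("greedy pruning matches exhaustive minimization on most small instances", {
  set.seed(77)
  n_trials <- 60
  hits <- 0
  for (trial in seq_len(n_trials)) {
    s1 <- sprintf("a%d", 1:sample(3:5, 1))
    s2 <- sprintf("b%d", 1:sample(3:5, 1))
    e1 <- t(combn(s1, 2)); e1 <- e1[runif(nrow(e1)) < 0.6, , drop = FALSE]
    e2 <- t(combn(s2, 2)); e2 <- e2[runif(nrow(e2)) < 0.6, , drop = FALSE]
    coll <- network_collection(list(ppi_network(e1, "s1", proteins = s1),
                                    ppi_network(e2, "s2", proteins = s2)))
    cross <- expand.grid(p = s1, q = s2, stringsAsFactors = FALSE)
    cross <- cross[runif(nrow(cross)) < 0.3, , drop = FALSE]
    cross$score <- round(runif(nrow(cross), 0.1, 1), 2)
    sim <- similarity_map(list(list(net_i = 1, net_j = 2, table = cross)), coll)
    cand <- complex_candidate(coll, sim, list(s1, s2), lambda = 1)
    greedy_f <- greedy_prune(cand)$cost
    exact_f <- exhaustive_min_cost(cand)
    expect_gte(greedy_f, exact_f - 1e-9)  # greedy can never beat the oracle
    if (abs(greedy_f - exact_f) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits / n_trials, 0.7)
})

test_that("post-processing removes duplicates, weak-homology and small complexes", {
  cx <- function(s1, s2, simsum) {
    conserved_complex(list(s1, s2), internal_similarity = simsum)
  }
  complexes <- list(
    cx(c("a1", "b1", "c1"), c("a2", "b2", "c2"), 2.0),
    cx(c("a1", "b1", "c1"), c("a2", "b2", "c2"), 2.0),   # exact duplicate
    cx(c("d1", "e1", "f1"), c("d2", "e2", "f2"), 0.05),  # below beta
    cx(c("g1", "h1"), c("g2", "h2", "i2"), 1.0))         # too small in species 1
  out <- postprocess(complexes, beta = 0.1, min_size_per_species = 3)
  expect_length(out, 1L)
  expect_identical(out[[1]]$sets[[1]], c("a1", "b1", "c1"))

  # with the size filter off, the small complex survives
  out2 <- postprocess(complexes, beta = 0.1, min_size_per_species = 0)
  expect_length(out2, 2L)
})

test_that("the pipeline is invariant to spine order and worker count", {
  w <- generate_planted_world(n_complexes = 4, n_background = 60, seed = 5)
  cfg <- clusterm_config()
  base <- run_clusterm(w$collection, w$sim, w$spines, cfg)
  perm <- spine_set(w$spines$members[rev(seq_len(w$spines$h)), ], w$collection)
  again <- run_clusterm(w$collection, w$sim, perm, cfg)
  sig <- function(l) vapply(l, clusterm:::complex_signature, "")
  expect_identical(sig(base), sig(again))
  par2 <- run_clusterm(w$collection, w$sim, w$spines, cfg, workers = 2)
  expect_identical(sig(base), sig(par2))

  empty <- spine_set(matrix(character(), ncol = 2), w$collection)
  expect_length(run_clusterm(w$collection, w$sim, empty, cfg), 0L)
})
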