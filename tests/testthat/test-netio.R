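test_that("edge-list reading collapses duplicates, drops self-loops, counts degrees", {
  f <- withr::local_tempfile(lines = c("a b", "b c", "a b"))
  net <- read_edge_list(f, "x")
  expect_setequal(net_proteins(net), c("a", "b", "c"))
  expect_equal(nrow(net_edges(net)), 2L)
  expect_equal(unname(net_degree(net)["b"]), 2L)

  f2 <- withr::local_tempfile(lines = c("a a", "a b"))
  expect_warning(net2 <- read_edge_list(f2, "x"), "self-loop")
  expect_setequal(net_proteins(net2), c("a", "b"))
  expect_equal(nrow(net_edges(net2)), 1L)

  f3 <- withr::local_tempfile(lines = c("a b", "# comment", "b c", "c d", "d e"))
  net3 <- read_edge_list(f3, "x")
  expect_equal(unname(net_degree(net3)[c("a", "b", "c", "d", "e")]),
               c(1L, 2L, 2L, 2L, 1L))

  f4 <- withr::local_tempfile(lines = c("a b", "lonely"))
  expect_error(read_edge_list(f4, "x"), "line 2")
})

test_that("graph reading is order-independent", {
  lines <- c("a b", "b c", "c d", "b d", "a e")
  f1 <- withr::local_tempfile(lines = lines)
  f2 <- withr::local_tempfile(lines = rev(lines))
  n1 <- read_edge_list(f1, "x")
  n2 <- read_edge_list(f2, "x")
  expect_identical(net_proteins(n1), net_proteins(n2))
  expect_identical(net_edges(n1)[order(net_edges(n1)[, 1], net_edges(n1)[, 2]), ],
                   net_edges(n2)[order(net_edges(n2)[, 1], net_edges(n2)[, 2]), ])
})

test_that("bit-score normalization follows the geometric self-score rule", {
  hits <- data.frame(p = "p", q = "q", bitscore = 100)
  ss <- c(p = 100, q = 400)
  out <- normalize_bitscores(hits, ss)
  expect_equal(out$score, 0.5)

  # self pair normalizes to 1
  out2 <- normalize_bitscores(data.frame(p = "p", q = "p", bitscore = 200),
                              c(p = 200))
  expect_equal(out2$score, 1)

  # sub-threshold pair discarded
  out3 <- normalize_bitscores(data.frame(p = "p", q = "q", bitscore = 10),
                              c(p = 100, q = 400), threshold = 0.1)
  expect_equal(nrow(out3), 0L)

  # highest bit score kept for repeated hits (both orientations)
  out4 <- normalize_bitscores(
    data.frame(p = c("p", "q"), q = c("q", "p"), bitscore = c(80, 120)),
    c(p = 100, q = 400))
  expect_equal(out4$score, 120 / sqrt(100 * 400))

  expect_error(normalize_bitscores(hits, c(p = 100)), "missing self-score.*q")
  expect_error(normalize_bitscores(hits, c(p = 100, q = -1)), "non-positive")
})

test_that("bit-score normalization is scale invariant", {
  set.seed(1)
  prots <- letters[1:6]
  hits <- expand.grid(p = prots[1:3], q = prots[4:6], stringsAsFactors = FALSE)
  hits$bitscore <- runif(nrow(hits), 10, 300)
  ss <- setNames(runif(6, 200, 500), prots)
  a <- normalize_bitscores(hits, ss, threshold = 0)
  hits2 <- hits; hits2$bitscore <- hits2$bitscore * 7.3
  b <- normalize_bitscores(hits2, ss * 7.3, threshold = 0)
  expect_equal(a, b)
})

test_that("similarity lookups are symmetric and absent pairs score zero", {
  coll <- network_collection(list(triangle_net(c("a1", "b1", "c1"), "s1"),
                                  triangle_net(c("a2", "b2", "c2"), "s2")))
  sim <- similarity_map(list(list(net_i = 1, net_j = 2,
                                  table = data.frame(p = "a1", q = "b2", score = 0.4))),
                        coll)
  expect_equal(sim_get(sim, 1, "a1", 2, "b2"), 0.4)
  expect_equal(sim_get(sim, 2, "b2", 1, "a1"), 0.4)
  expect_equal(sim_get(sim, 1, "a1", 2, "c2"), 0)
  expect_true(all(sim$entries$score >= sim$threshold))
})

test_that("writers and readers round-trip complexes, spines and similarity", {
  cxs <- list(cxp(c("a1", "b1", "c1"), c("a2", "b2")),
              cxp("x1", c("y2", "z2")),
              cxp(c("m1", "n1"), "q2"))
  f <- withr::local_tempfile()
  write_complexes(cxs, f)
  back <- read_complexes(f)
  expect_equal(lapply(back, `[[`, "sets"), lapply(cxs, `[[`, "sets"))

  coll <- network_collection(list(triangle_net(c("a1", "b1", "c1"), "s1"),
                                  triangle_net(c("a2", "b2", "c2"), "s2")))
  sp <- spine_set(rbind(c("a1", "a2"), c("b1", "b2")), coll)
  f2 <- withr::local_tempfile()
  write_spines(sp, f2)
  expect_identical(unname(read_spines(f2, coll)$members), unname(sp$members))

  sim <- similarity_map(list(list(net_i = 1, net_j = 2,
                                  table = data.frame(p = c("a1", "b1"),
                                                     q = c("a2", "c2"),
                                                     score = c(0.5, 0.25)))), coll)
  f3 <- withr::local_tempfile()
  write_similarity_tsv(sim, coll, f3)
  sim2 <- read_similarity_tsv(f3, coll)
  expect_equal(sim2$entries, sim$entries)
})

test_that("spine files are validated against the collection", {
  coll <- network_collection(list(triangle_net(c("a1", "b1", "c1"), "s1"),
                                  triangle_net(c("a2", "b2", "c2"), "s2")))
  f <- withr::local_tempfile(lines = c("a1\ta2\tb2"))
  expect_error(read_spines(f, coll), "arity 3")
  f2 <- withr::local_tempfile(lines = c("a1\ta2", "a1\ta2", "b1\tb2"))
  expect_warning(sp <- read_spines(f2, coll), "duplicated")
  expect_equal(sp$h, 2L)
  f3 <- withr::local_tempfile(lines = c("a1\tzz"))
  expect_error(read_spines(f3, coll), "row 1, column 2")
})

test_that("GAF reading keeps evidence codes verbatim", {
  gaf_line <- function(prot, go, ev, aspect) {
    paste(c("DB", prot, prot, "", go, "REF:1", ev, "", aspect,
            rep("", 8)), collapse = "\t")
  }
  f <- withr::local_tempfile(lines = c(
    "!gaf-version: 2.1",
    gaf_line("P1", "GO:0001", "IEA", "P"),
    gaf_line("P2", "GO:0001", "EXP", "P")))
  ann <- read_gaf(f)
  expect_equal(nrow(ann$assignments), 2L)
  expect_true("IEA" %in% ann$assignments$evidence)
  expect_equal(unname(ann$term_sizes["GO:0001"]), 2L)
})
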