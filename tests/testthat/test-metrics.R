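test_that("neighborhood affinity follows the squared-overlap formula", {
  expect_equal(neighborhood_affinity(c("a", "b"), c("a", "b")), 1)
  expect_equal(neighborhood_affinity(c("a", "b"), c("c", "d")), 0)
  expect_equal(neighborhood_affinity(c("a", "b", "c"), c("b", "c", "d")), 4 / 9)
  expect_error(neighborhood_affinity(character(0), "a"), "non-empty")
})

test_that("fraction of matched references requires both species to pass tau", {
  refs <- list(ref(c("a1", "b1", "c1"), c("a2", "b2", "c2")),
               ref(c("x1", "y1", "z1"), c("x2", "y2", "z2")))
  preds <- list(cxp(c("a1", "b1", "c1"), c("a2", "b2", "c2")))
  expect_equal(fraction_matched(refs, preds), 0.5)
  expect_equal(fraction_matched(refs, lapply(refs, function(r) cxp(r$set_1, r$set_2))), 1)

  # species 1 at 0.3 but species 2 at about 0.2: no match at tau 0.25
  r <- list(ref(sprintf("a%d", 1:10), sprintf("b%d", 1:5)))
  p <- list(cxp(sprintf("a%d", 1:3), c("b1", "z2", "z3", "z4", "z5")))
  expect_equal(neighborhood_affinity(r[[1]]$set_1, p[[1]]$sets[[1]]), 0.3)
  expect_equal(neighborhood_affinity(r[[1]]$set_2, p[[1]]$sets[[2]]), 0.04)
  expect_equal(fraction_matched(r, p), 0)
  expect_error(fraction_matched(list(), preds), "non-empty")
})

test_that("Sn/PPV/Acc match the overlap-count definitions", {
  refs <- list(ref(c("a1", "b1", "c1"), c("a2", "b2", "c2")))
  pred <- list(cxp(c("a1", "b1"), c("a2", "b2")))
  sc <- accuracy_scores(refs, pred)
  expect_equal(unname(sc["sn"]), 4 / 6)
  expect_equal(unname(sc["ppv"]), 1)
  expect_equal(unname(sc["acc"]), sqrt(4 / 6))

  # perfect, disjoint and empty predictions
  refs2 <- list(ref(c("a1", "b1"), c("a2", "b2")), ref(c("x1", "y1"), c("x2", "y2")))
  perf <- lapply(refs2, function(r) cxp(r$set_1, r$set_2))
  expect_equal(unname(accuracy_scores(refs2, perf)), c(1, 1, 1))
  none <- list(cxp(c("q1", "r1"), c("q2", "r2")))
  expect_equal(unname(accuracy_scores(refs2, none)), c(0, 0, 0))
  expect_equal(unname(accuracy_scores(refs2, list())), c(0, 0, 0))
})

test_that("MMRC equals brute-force maximum matching on random instances", {
  refs1 <- list(ref(c("a1", "b1"), c("a2", "b2")))
  expect_equal(mmrc(refs1, list(cxp(c("a1", "b1"), c("a2", "b2")))), 1)

  refs2 <- list(ref(c("a1", "b1"), c("a2", "b2")), ref(c("x1", "y1"), c("x2", "y2")))
  preds2 <- list(cxp(c("a1", "b1"), c("a2", "b2")))
  expect_equal(mmrc(refs2, preds2), 0.5)

  # randomized cross-check against enumeration of all assignments
  set.seed(123)
  for (trial in 1:40) {
    n <- sample(1:7, 1); m <- sample(1:7, 1)
    universe1 <- sprintf("p%d", 1:12)
    universe2 <- sprintf("q%d", 1:12)
    refs <- lapply(seq_len(n), function(i) {
      ref(sample(universe1, sample(2:5, 1)), sample(universe2, sample(2:5, 1)))
    })
    preds <- lapply(seq_len(m), function(i) {
      cxp(sample(universe1, sample(2:5, 1)), sample(universe2, sample(2:5, 1)))
    })
    B <- matrix(0, n, m)
    for (j in seq_len(n)) for (i in seq_len(m)) {
      w1 <- neighborhood_affinity(refs[[j]]$set_1, preds[[i]]$sets[[1]])
      w2 <- neighborhood_affinity(refs[[j]]$set_2, preds[[i]]$sets[[2]])
      o <- if (w1 + w2 > 0) 2 * w1 * w2 / (w1 + w2) else 0
      B[j, i] <- if (o >= 0.25) o else 0
    }
    expect_equal(mmrc(refs, preds), brute_force_matching(B) / n, tolerance = 1e-9)
  }
})

test_that("metric bundle hits the identity and zero landmarks", {
  refs <- list(ref(c("a1", "b1", "c1"), c("a2", "b2", "c2")),
               ref(c("x1", "y1", "z1"), c("x2", "y2", "z2")))
  perf <- lapply(refs, function(r) cxp(r$set_1, r$set_2))
  rep1 <- evaluate_complexes(refs, perf)
  expect_equal(c(rep1$fraction, rep1$sn, rep1$ppv, rep1$acc, rep1$mmrc, rep1$composite),
               c(1, 1, 1, 1, 1, 3))
  rep0 <- evaluate_complexes(refs, list(cxp(c("u1", "v1"), c("u2", "v2"))))
  expect_equal(c(rep0$fraction, rep0$acc, rep0$mmrc, rep0$composite), c(0, 0, 0, 0))
  expect_equal(composite_score(0.5, 0.4, 0.3), 1.2)

  # invariance to ordering of references and predictions
  set.seed(4)
  preds <- c(perf, list(cxp(c("a1", "m1", "n1"), c("a2", "m2", "n2"))))
  a <- evaluate_complexes(refs, preds)
  b <- evaluate_complexes(rev(refs), rev(preds))
  expect_equal(unclass(a), unclass(b))
})

test_that("high-level terms are filtered by information content and evidence", {
  mk <- function(protein, term, evidence, aspect = "P") {
    data.frame(protein = protein, term = term, evidence = evidence,
               aspect = aspect, stringsAsFactors = FALSE)
  }
  # 1000 root proteins: term g100 has 100 (IC ~ 2.303 > 2), term gall has all
  prots <- sprintf("P%04d", 1:1000)
  ann <- annotation_table(rbind(
    mk(prots, "GO:ALL", "EXP"),
    mk(prots[1:100], "GO:0100", "EXP")))
  hl <- high_level_terms(ann, ic_threshold = 2)
  expect_true("GO:0100" %in% hl)
  expect_false("GO:ALL" %in% hl)

  # a term supported only by IEA disappears after evidence filtering
  ann2 <- annotation_table(rbind(
    mk(prots, "GO:ALL", "EXP"),
    mk(prots[1:50], "GO:IEAONLY", "IEA"),
    mk(prots[1:100], "GO:0100", "EXP")))
  hl2 <- high_level_terms(ann2)
  expect_false("GO:IEAONLY" %in% hl2)
})

test_that("normalized entropy rewards annotation coherence", {
  mk <- function(protein, term) {
    data.frame(protein = protein, term = term, evidence = "EXP", aspect = "P",
               stringsAsFactors = FALSE)
  }
  # all proteins share one term: NE = 0
  ann <- annotation_table(mk(c("p1", "p2", "p3"), "GO:1"))
  cx1 <- conserved_complex(list(c("p1", "p2", "p3"), character(0)))
  expect_equal(mne(list(cx1), ann), 0)

  # uniform over 4 terms: NE = 1
  ann2 <- annotation_table(mk(paste0("p", 1:4), paste0("GO:", 1:4)))
  cx2 <- conserved_complex(list(paste0("p", 1:4), character(0)))
  expect_equal(mne(list(cx2), ann2), 1)

  # split 3:1 over two terms: NE = -(0.75 log 0.75 + 0.25 log 0.25)/log 2
  ann3 <- annotation_table(mk(paste0("p", 1:4), c("GO:1", "GO:1", "GO:1", "GO:2")))
  cx3 <- conserved_complex(list(paste0("p", 1:4), character(0)))
  expect_equal(mne(list(cx3), ann3),
               -(0.75 * log(0.75) + 0.25 * log(0.25)) / log(2))

  # unannotated complexes are skipped with a warning
  cx4 <- conserved_complex(list("zz", character(0)))
  expect_warning(v <- mne(list(cx3, cx4), ann3), "skipped")
  expect_equal(v, mne(list(cx3), ann3))
})

test_that("coverage counts distinct namespaced proteins of qualifying complexes", {
  expect_equal(coverage(list()), 0L)
  big <- conserved_complex(list(c("a1", "b1", "c1"), c("a2", "b2", "c2")))
  expect_equal(coverage(list(big)), 6L)
  small <- conserved_complex(list(c("a1", "b1"), c("a2", "b2", "c2")))
  expect_equal(coverage(list(big, small)), 6L)  # small one fails the filter
  shared <- conserved_complex(list(c("a1", "x1", "y1"), c("x2", "y2", "z2")))
  expect_equal(coverage(list(big, shared)), 11L)  # a1 counted once
  expect_equal(coverage(list(big, shared), distinct = FALSE), 12L)
})

test_that("reference pairs require half the species-2 complex to share the term", {
  mk <- function(protein, term) {
    data.frame(protein = protein, term = term, evidence = "EXP", aspect = "P",
               stringsAsFactors = FALSE)
  }
  ann <- annotation_table(mk(c("h1", "h2"), "GO:T"))
  c1 <- list(list(proteins = c("y1", "y2", "y3"), term = "GO:T"))
  paired <- build_reference_pairs(c1, list(c("h1", "h2", "h3", "h4")), ann)
  expect_length(paired, 1L)
  expect_identical(paired[[1]]$label, "GO:T")
  # only 1 of 4 annotated: below half
  ann2 <- annotation_table(mk("h1", "GO:T"))
  expect_length(build_reference_pairs(c1, list(c("h1", "h2", "h3", "h4")), ann2), 0L)
  # term annotating no species-2 protein
  c2 <- list(list(proteins = c("y1", "y2"), term = "GO:NONE"))
  expect_length(build_reference_pairs(c2, list(c("h1", "h2")), ann), 0L)
})
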