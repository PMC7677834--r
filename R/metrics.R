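# Evaluation suite for pairwise conserved-complex prediction: neighborhood
# affinity matching, complex-wise Sn/PPV/Acc, maximum matching ratio for
# conserved complexes (MMRC), plus GO-based consistency (MNE), coverage and
# reference-pair construction. The pairwise metrics are defined for k = 2;
# MNE and coverage apply to any k.

#' A reference conserved complex pair
#' @param set_1 protein set in species 1 (non-empty).
#' @param set_2 protein set in species 2 (non-empty).
#' @param label optional GO term or name.
#' @return object of class `reference_pair`.
#' @export
reference_pair <- function(set_1, set_2, label = NA_character_) {
  set_1 <- sort(unique(as.character(set_1)))
  set_2 <- sort(unique(as.character(set_2)))
  stopifnot(length(set_1) > 0, length(set_2) > 0)
  structure(list(set_1 = set_1, set_2 = set_2, label = label),
            class = "reference_pair")
}

#' Neighborhood affinity of two protein sets
#'
#' \deqn{w(X,Y) = |X \cap Y|^2 / (|X|\,|Y|)}
#'
#' @param x,y non-empty protein sets.
#' @return affinity in `[0,1]`.
#' @export
neighborhood_affinity <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (!length(x) || !length(y)) stop("protein sets must be non-empty")
  length(intersect(x, y))^2 / (length(x) * length(y))
}

pred_sets <- function(prediction) {
  if (inherits(prediction, "conserved_complex")) prediction$sets else prediction
}

#' Fraction of matched reference conserved complexes
#'
#' A reference `A = (A1, A2)` counts as matched if some prediction
#' `B = (B1, B2)` has neighborhood affinity at least `tau` in both species
#' simultaneously.
#'
#' @param references list of `reference_pair`.
#' @param predictions list of two-species `conserved_complex` (or plain
#'   two-set lists), species-aligned with the references.
#' @param tau affinity threshold (default 0.25).
#' @return fraction in `[0,1]`.
#' @export
fraction_matched <- function(references, predictions, tau = 0.25) {
  if (!length(references)) stop("reference list must be non-empty")
  matched <- vapply(references, function(ref) {
    for (pr in predictions) {
      ps <- pred_sets(pr)
      if (!length(ps[[1]]) || !length(ps[[2]])) next
      if (neighborhood_affinity(ref$set_1, ps[[1]]) >= tau &&
          neighborhood_affinity(ref$set_2, ps[[2]]) >= tau) return(TRUE)
    }
    FALSE
  }, TRUE)
  mean(matched)
}

# overlap counts with species namespacing so cross-species unions are disjoint
overlap_matrix <- function(references, predictions) {
  n <- length(references); m <- length(predictions)
  t_ij <- matrix(0, nrow = m, ncol = n)
  for (i in seq_len(m)) {
    ps <- pred_sets(predictions[[i]])
    for (j in seq_len(n)) {
      t_ij[i, j] <- length(intersect(references[[j]]$set_1, ps[[1]])) +
        length(intersect(references[[j]]$set_2, ps[[2]]))
    }
  }
  t_ij
}

#' Complex-wise sensitivity, positive predictive value and accuracy
#'
#' With overlap counts \eqn{t_{ij} = |A_1^j \cap B_1^i| + |A_2^j \cap B_2^i|}
#' and reference sizes \eqn{w_j = |A_1^j| + |A_2^j|}:
#' \deqn{Sn = \sum_j \max_i t_{ij} / \sum_j w_j, \quad
#'   PPV = \sum_i \max_j t_{ij} / \sum_i \sum_j t_{ij}, \quad
#'   Acc = \sqrt{Sn\, PPV}.}
#' A zero PPV denominator (no overlap at all) yields PPV = 0.
#'
#' @inheritParams fraction_matched
#' @return named numeric vector `c(sn=, ppv=, acc=)`.
#' @export
accuracy_scores <- function(references, predictions) {
  if (!length(references)) stop("reference list must be non-empty")
  w <- vapply(references, function(r) length(r$set_1) + length(r$set_2), 0)
  if (!length(predictions)) return(c(sn = 0, ppv = 0, acc = 0))
  t_ij <- overlap_matrix(references, predictions)
  sn <- sum(apply(t_ij, 2, max)) / sum(w)
  denom <- sum(t_ij)
  ppv <- if (denom > 0) sum(apply(t_ij, 1, max)) / denom else 0
  c(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Maximum matching ratio for conserved complexes
#'
#' Each reference-prediction pair is weighted by the harmonic mean of the two
#' per-species neighborhood affinities,
#' \deqn{o(A,B) = 2 w(A_1,B_1) w(A_2,B_2) / (w(A_1,B_1) + w(A_2,B_2)),}
#' defined as 0 when both affinities are 0. Edges with weight below `tau`
#' are dropped, a maximum-weight bipartite matching (each reference and each
#' prediction used at most once) is computed, and its total weight is
#' divided by the number of references.
#'
#' @inheritParams fraction_matched
#' @return MMRC in `[0,1]`.
#' @export
mmrc <- function(references, predictions, tau = 0.25) {
  if (!length(references)) stop("reference list must be non-empty")
  n <- length(references); m <- length(predictions)
  if (m == 0) return(0)
  edges <- list()
  for (j in seq_len(n)) {
    for (i in seq_len(m)) {
      ps <- pred_sets(predictions[[i]])
      if (!length(ps[[1]]) || !length(ps[[2]])) next
      w1 <- neighborhood_affinity(references[[j]]$set_1, ps[[1]])
      w2 <- neighborhood_affinity(references[[j]]$set_2, ps[[2]])
      o <- if (w1 + w2 > 0) 2 * w1 * w2 / (w1 + w2) else 0
      if (o >= tau) edges[[length(edges) + 1L]] <- c(j, n + i, o)
    }
  }
  if (!length(edges)) return(0)
  em <- do.call(rbind, edges)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n), rep(TRUE, m)),
    edges = as.vector(t(em[, 1:2, drop = FALSE])))
  mt <- igraph::max_bipartite_match(g, weights = em[, 3])
  mt$matching_weight / n
}

#' Composite evaluation score
#' @param fraction,acc,mmrc component scores.
#' @return `fraction + acc + mmrc`, in `[0, 3]`.
#' @export
composite_score <- function(fraction, acc, mmrc) fraction + acc + mmrc

#' Evaluate predictions against references
#'
#' Bundles [fraction_matched()], [accuracy_scores()], [mmrc()] and the
#' composite score into one report.
#'
#' @inheritParams fraction_matched
#' @return object of class `complex_match_report`: named list with fields
#'   `fraction`, `sn`, `ppv`, `acc`, `mmrc`, `composite`.
#' @export
evaluate_complexes <- function(references, predictions, tau = 0.25) {
  frac <- fraction_matched(references, predictions, tau)
  acc3 <- accuracy_scores(references, predictions)
  mm <- mmrc(references, predictions, tau)
  structure(list(fraction = frac, sn = unname(acc3["sn"]),
                 ppv = unname(acc3["ppv"]), acc = unname(acc3["acc"]),
                 mmrc = mm,
                 composite = composite_score(frac, unname(acc3["acc"]), mm)),
            class = "complex_match_report")
}

#' @export
print.complex_match_report <- function(x, ...) {
  cat(sprintf(paste0("<complex_match_report: fraction %.3f, Sn %.3f, PPV %.3f, ",
                     "Acc %.3f, MMRC %.3f, composite %.3f>\n"),
              x$fraction, x$sn, x$ppv, x$acc, x$mmrc, x$composite))
  invisible(x)
}

# ---- GO-based metrics --------------------------------------------------------

#' High-level GO terms by information content
#'
#' Drops annotations with excluded evidence codes, recomputes term and
#' root-namespace sizes, and keeps terms whose information content
#' \eqn{IC = -\log(|g|/|root|)} exceeds `ic_threshold`. Natural log by
#' default (`log_base`); the threshold of 2 then corresponds to terms
#' annotating less than \eqn{e^{-2} \approx 13.5\%} of their namespace.
#'
#' @param annotations an `annotation_table`.
#' @param ic_threshold IC cutoff (default 2).
#' @param excluded_evidence evidence codes to drop (default IEA, IPI, ISS:
#'   electronic, interaction-inferred and sequence-similarity-inferred
#'   annotations, which would leak the algorithm's own inputs into the
#'   evaluation).
#' @param log_base base of the logarithm (default `exp(1)`).
#' @return character vector of high-level GO term identifiers.
#' @export
high_level_terms <- function(annotations, ic_threshold = 2,
                             excluded_evidence = c("IEA", "IPI", "ISS"),
                             log_base = exp(1)) {
  a <- annotations$assignments
  a <- a[!(a$evidence %in% excluded_evidence), , drop = FALSE]
  if (!nrow(a)) return(character(0))
  term_sizes <- tapply(a$protein, a$term, function(p) length(unique(p)))
  aspect_of <- tapply(a$aspect, a$term, function(x) x[1])
  root_sizes <- tapply(a$protein, a$aspect, function(p) length(unique(p)))
  ic <- -log(as.numeric(term_sizes) / as.numeric(root_sizes[aspect_of]),
             base = log_base)
  names(ic) <- names(term_sizes)
  names(ic)[!is.na(ic) & ic > ic_threshold]
}

#' Mean normalized entropy of GO annotations in complexes
#'
#' For a complex annotated with d distinct (filtered) terms and
#' protein-term assignment fractions \eqn{p_1..p_d}:
#' \deqn{NE = -\frac{1}{\log d} \sum_j p_j \log p_j,}
#' with NE = 0 when d = 1. MNE is the mean over complexes; complexes with no
#' annotated protein are skipped with a warning. Lower values mean more
#' functionally coherent complexes.
#'
#' @param complexes list of `conserved_complex`.
#' @param annotations an `annotation_table`.
#' @param term_filter optional character vector of admissible terms (e.g.
#'   from [high_level_terms()]); `NULL` uses all terms.
#' @return the MNE value, or `NA` if no complex could be scored.
#' @export
mne <- function(complexes, annotations, term_filter = NULL) {
  a <- annotations$assignments
  if (!is.null(term_filter)) a <- a[a$term %in% term_filter, , drop = FALSE]
  nes <- vapply(complexes, function(cx) {
    prots <- unlist(cx$sets, use.names = FALSE)
    sub <- a[a$protein %in% prots, , drop = FALSE]
    if (!nrow(sub)) return(NA_real_)
    counts <- table(sub$term)
    d <- length(counts)
    if (d == 1L) return(0)
    p <- as.numeric(counts) / sum(counts)
    -sum(p * log(p)) / log(d)
  }, 0)
  if (anyNA(nes)) {
    warning(sprintf("%d complex(es) with no annotated protein skipped", sum(is.na(nes))))
  }
  if (all(is.na(nes))) return(NA_real_)
  mean(nes, na.rm = TRUE)
}

#' Protein coverage of the predictions
#'
#' Number of distinct proteins (namespaced by species) appearing in
#' complexes that have at least `min_size_per_species` proteins in every
#' species. With `distinct = FALSE`, occurrences are summed per complex
#' instead.
#'
#' @param complexes list of `conserved_complex`.
#' @param min_size_per_species qualifying size (default 3).
#' @param distinct count each protein once across complexes (default TRUE).
#' @return integer count.
#' @export
coverage <- function(complexes, min_size_per_species = 3L, distinct = TRUE) {
  ok <- Filter(function(cx) {
    all(vapply(cx$sets, length, 1L) >= min_size_per_species)
  }, complexes)
  if (!length(ok)) return(0L)
  tagged <- lapply(ok, function(cx) {
    unlist(lapply(seq_along(cx$sets), function(j) paste0(j, "\r", cx$sets[[j]])),
           use.names = FALSE)
  })
  if (distinct) length(unique(unlist(tagged))) else length(unlist(tagged))
}

#' Build reference conserved pairs from annotated complex catalogs
#'
#' Mirrors the construction of a cross-species gold standard from two
#' single-species complex catalogs: a species-1 complex carrying a GO term
#' is paired with a species-2 complex when at least half of the species-2
#' complex's proteins are annotated to that term. One species-2 complex may
#' pair with several species-1 complexes sharing the term.
#'
#' @param complexes_1 list of `list(proteins=, term=)` for species 1.
#' @param complexes_2 list of character vectors (species-2 complexes).
#' @param annotations an `annotation_table` for species-2 proteins.
#' @return list of `reference_pair`.
#' @export
build_reference_pairs <- function(complexes_1, complexes_2, annotations) {
  a <- annotations$assignments
  out <- list()
  for (c1 in complexes_1) {
    term <- c1$term
    annotated <- unique(a$protein[a$term == term])
    for (c2 in complexes_2) {
      c2 <- unique(c2)
      if (length(c2) == 0) next
      if (sum(c2 %in% annotated) >= length(c2) / 2) {
        out[[length(out) + 1L]] <- reference_pair(c1$proteins, c2, label = term)
      }
    }
  }
  out
}
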