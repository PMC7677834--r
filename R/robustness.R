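# Robustness harness: degree-preserving rewiring of PPI edges and of the
# homology bipartite graph (repeated double-edge swaps, the standard
# rewiring null model), a replicate-and-average protocol over the four noise
# conditions, and the grid-search parameter sampler. All randomness comes
# from R's RNG; callers seed it (replicate_and_average does so itself).

#' Perturbation specification
#' @param edge_fraction fraction of PPI edges to displace (default 0.1).
#' @param homology_fraction fraction of homology pairs to displace
#'   (default 0.1).
#' @param replicates perturbed replicates per condition (default 10).
#' @param random_seed base seed (default 1).
#' @return a `perturbation_spec` list.
#' @export
perturbation_spec <- function(edge_fraction = 0.1, homology_fraction = 0.1,
                              replicates = 10L, random_seed = 1L) {
  stopifnot(edge_fraction >= 0, edge_fraction <= 1,
            homology_fraction >= 0, homology_fraction <= 1, replicates >= 1)
  structure(list(edge_fraction = edge_fraction,
                 homology_fraction = homology_fraction,
                 replicates = as.integer(replicates),
                 random_seed = as.integer(random_seed)),
            class = "perturbation_spec")
}

#' Degree-preserving rewiring of a PPI network
#'
#' Repeated double-edge swaps: two edges (a,b) and (c,d) are replaced by
#' (a,d) and (c,b); swaps creating self-loops or duplicate edges are
#' rejected. Swapping preserves every degree exactly. Swaps continue until
#' the number of original edges no longer present reaches
#' `ceiling(fraction * |E|)`, or a retry cap is hit (best effort with a
#' warning).
#'
#' @param network a `ppi_network`.
#' @param fraction target fraction of displaced original edges, in `[0,1]`.
#' @return a rewired `ppi_network` with identical protein set and degree
#'   sequence.
#' @export
rewire_network <- function(network, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  edges <- net_edges(network)
  ne <- nrow(edges)
  if (fraction == 0 || ne < 2) return(network)
  target <- ceiling(fraction * ne)
  ekey <- function(a, b) ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  present <- new.env(parent = emptyenv(), size = ne * 2L)
  orig <- new.env(parent = emptyenv(), size = ne * 2L)
  for (r in seq_len(ne)) {
    k <- ekey(edges[r, 1], edges[r, 2])
    assign(k, TRUE, envir = present)
    assign(k, TRUE, envir = orig)
  }
  displaced <- 0L
  attempts <- 0L
  cap <- 200L * target + 1000L
  while (displaced < target && attempts < cap) {
    attempts <- attempts + 1L
    r12 <- sample.int(ne, 2L)
    a <- edges[r12[1], 1]; b <- edges[r12[1], 2]
    c_ <- edges[r12[2], 1]; d <- edges[r12[2], 2]
    if (runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }  # random orientation
    # proposed: (a,d), (c_,b)
    if (a == d || c_ == b) next
    k_ad <- ekey(a, d); k_cb <- ekey(c_, b)
    if (k_ad == k_cb) next
    if (!is.null(get0(k_ad, envir = present)) ||
        !is.null(get0(k_cb, envir = present))) next
    k1 <- ekey(a, b); k2 <- ekey(c_, d)
    rm(list = c(k1, k2), envir = present)
    assign(k_ad, TRUE, envir = present)
    assign(k_cb, TRUE, envir = present)
    if (!is.null(get0(k1, envir = orig))) displaced <- displaced + 1L
    if (!is.null(get0(k2, envir = orig))) displaced <- displaced + 1L
    if (!is.null(get0(k_ad, envir = orig))) displaced <- displaced - 1L
    if (!is.null(get0(k_cb, envir = orig))) displaced <- displaced - 1L
    edges[r12[1], ] <- sort(c(a, d))
    edges[r12[2], ] <- sort(c(c_, b))
  }
  if (displaced < target) {
    warning(sprintf("rewiring reached %d of %d target displaced edges", displaced, target))
  }
  ppi_network(edges, species = network$species, proteins = net_proteins(network))
}

#' Degree-preserving perturbation of the homology bipartite graph
#'
#' Treats the similarity pairs of each network pair as a bipartite graph and
#' applies the same double-swap procedure: pairs (p1,q1) and (p2,q2) become
#' (p1,q2) and (p2,q1), preserving both side's degree sequences. Each new
#' pair inherits the score of the original pair sharing its left endpoint.
#'
#' @param sim a `similarity_map`.
#' @param fraction target fraction of displaced pairs, in `[0,1]`.
#' @return a perturbed `similarity_map`.
#' @export
perturb_homology <- function(sim, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0 || nrow(sim$entries) == 0) return(sim)
  ent <- sim$entries
  keyf <- function(i, j) paste(i, j, sep = "\r")
  out <- list()
  for (grp in split(seq_len(nrow(ent)), keyf(ent$net_i, ent$net_j))) {
    e <- ent[grp, , drop = FALSE]
    ne <- nrow(e)
    if (ne < 2) { out[[length(out) + 1L]] <- e; next }
    target <- ceiling(fraction * ne)
    p <- e$p; q <- e$q; s <- e$score
    present <- new.env(parent = emptyenv(), size = ne * 2L)
    orig <- new.env(parent = emptyenv(), size = ne * 2L)
    for (r in seq_len(ne)) {
      k <- keyf(p[r], q[r])
      assign(k, TRUE, envir = present); assign(k, TRUE, envir = orig)
    }
    displaced <- 0L; attempts <- 0L
    cap <- 200L * target + 1000L
    while (displaced < target && attempts < cap) {
      attempts <- attempts + 1L
      r12 <- sample.int(ne, 2L)
      r1 <- r12[1]; r2 <- r12[2]
      if (p[r1] == p[r2] || q[r1] == q[r2]) next
      k_new1 <- keyf(p[r1], q[r2]); k_new2 <- keyf(p[r2], q[r1])
      if (!is.null(get0(k_new1, envir = present)) ||
          !is.null(get0(k_new2, envir = present))) next
      k_old1 <- keyf(p[r1], q[r1]); k_old2 <- keyf(p[r2], q[r2])
      rm(list = c(k_old1, k_old2), envir = present)
      assign(k_new1, TRUE, envir = present)
      assign(k_new2, TRUE, envir = present)
      if (!is.null(get0(k_old1, envir = orig))) displaced <- displaced + 1L
      if (!is.null(get0(k_old2, envir = orig))) displaced <- displaced + 1L
      if (!is.null(get0(k_new1, envir = orig))) displaced <- displaced - 1L
      if (!is.null(get0(k_new2, envir = orig))) displaced <- displaced - 1L
      tmp <- q[r1]; q[r1] <- q[r2]; q[r2] <- tmp
      # scores follow the left endpoint, so s is unchanged
    }
    if (displaced < target) {
      warning(sprintf("homology perturbation reached %d of %d target displaced pairs",
                      displaced, target))
    }
    out[[length(out) + 1L]] <- data.frame(net_i = e$net_i, net_j = e$net_j,
                                          p = p, q = q, score = s,
                                          stringsAsFactors = FALSE)
  }
  sim_from_entries(do.call(rbind, out), sim$threshold)
}

#' Run the pipeline over clean and perturbed replicates
#'
#' Four noise conditions are evaluated: clean, topological noise only,
#' homology noise only, and both. For each condition, `replicates`
#' perturbed datasets are generated (the clean condition is deterministic),
#' the pipeline is run, the evaluator is applied, and metric means and
#' standard deviations are reported, together with the mean/sd of the
#' per-condition composite scores.
#'
#' @param collection a `network_collection`.
#' @param sim a `similarity_map`.
#' @param spec a [perturbation_spec()].
#' @param pipeline function `(collection, sim) -> predictions`.
#' @param evaluator function `(predictions) -> named numeric vector` (e.g.
#'   wrapping [evaluate_complexes()]).
#' @return list with `by_condition` (data frame: condition, metric, mean,
#'   sd) and `composite` (mean and sd of the per-condition mean composite
#'   scores, when the evaluator reports a `composite` field).
#' @export
replicate_and_average <- function(collection, sim, spec, pipeline, evaluator) {
  conditions <- list(
    clean = c(0, 0),
    topological = c(spec$edge_fraction, 0),
    homology = c(0, spec$homology_fraction),
    both = c(spec$edge_fraction, spec$homology_fraction))
  rows <- list()
  cond_means <- list()
  for (ci in seq_along(conditions)) {
    fr <- conditions[[ci]]
    nrep <- if (all(fr == 0)) 1L else spec$replicates
    scores <- list()
    for (r in seq_len(nrep)) {
      set.seed(spec$random_seed + 1000L * ci + r)
      coll_r <- collection
      sim_r <- sim
      if (fr[1] > 0) {
        coll_r <- network_collection(lapply(collection$networks, rewire_network,
                                            fraction = fr[1]))
      }
      if (fr[2] > 0) sim_r <- perturb_homology(sim, fr[2])
      preds <- pipeline(coll_r, sim_r)
      scores[[r]] <- unlist(evaluator(preds))
    }
    sm <- do.call(rbind, scores)
    mu <- colMeans(sm)
    sdv <- apply(sm, 2, sd)
    sdv[is.na(sdv)] <- 0
    rows[[ci]] <- data.frame(condition = names(conditions)[ci],
                             metric = colnames(sm), mean = as.numeric(mu),
                             sd = as.numeric(sdv), stringsAsFactors = FALSE)
    cond_means[[ci]] <- mu
  }
  by_condition <- do.call(rbind, rows)
  rownames(by_condition) <- NULL
  composite <- NULL
  if (all(vapply(cond_means, function(m) "composite" %in% names(m), TRUE))) {
    comps <- vapply(cond_means, `[[`, 0, "composite")
    composite <- c(mean = mean(comps), sd = sd(comps))
  }
  list(by_condition = by_condition, composite = composite)
}

#' Grid-search parameter sampler
#'
#' Given a budget of at most N parameter combinations over k parameters,
#' samples \eqn{n = \lfloor N^{1/k} \rfloor} evenly spaced values per
#' parameter (both endpoints included) and returns the full Cartesian
#' product, of size \eqn{n^k \le N}.
#'
#' @param parameters named list of `c(min, max)` ranges.
#' @param budget maximum number of combinations N (default 100).
#' @return data frame with one column per parameter and one row per sampled
#'   combination.
#' @export
grid_sample <- function(parameters, budget = 100L) {
  k <- length(parameters)
  stopifnot(k >= 1)
  n <- as.integer(floor(budget^(1 / k) + 1e-9))
  if (n < 1) stop("budget too small: no grid point per parameter")
  values <- lapply(parameters, function(rg) {
    stopifnot(length(rg) == 2, rg[1] < rg[2])
    if (n == 1L) (rg[1] + rg[2]) / 2 else seq(rg[1], rg[2], length.out = n)
  })
  out <- expand.grid(values, KEEP.OUT.ATTRS = FALSE)
  names(out) <- names(parameters)
  out
}
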