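# Task 2: assemble the per-network minimum-conductance sets for a spine into
# one candidate, score selections with a cost that rewards within-network
# interaction density and cross-network sequence homology, and greedily prune
# proteins until no single removal improves the cost.

#' Algorithm configuration
#'
#' @param m personalized-PageRank neighborhood size (proteins per network
#'   around each spine protein); default 20.
#' @param restart PageRank restart probability; default 0.15.
#' @param tolerance PageRank push tolerance (residual per unit degree);
#'   default 1e-4.
#' @param lambda weight of the homology term against the density term;
#'   default 10 (the middle of the 1/10/100 sweep).
#' @param beta post-filter: drop complexes whose internal similarity sum is
#'   below this; default 0.1.
#' @param min_size_per_species post-filter: drop complexes with fewer
#'   proteins than this in any species (0 disables); default 3.
#' @param exhaustive_cap largest neighborhood for exhaustive fallback;
#'   default 15.
#' @param solver minimum-conductance solver mode, `"exact"` (default,
#'   alias `"mip"`) or `"exhaustive"`.
#' @param seed integer seed for any randomized component; default 1.
#' @return a `clusterm_config` list.
#' @export
clusterm_config <- function(m = 20L, restart = 0.15, tolerance = 1e-4,
                            lambda = 10, beta = 0.1, min_size_per_species = 3L,
                            exhaustive_cap = 15L, solver = "exact", seed = 1L) {
  stopifnot(m >= 1, restart > 0, restart < 1, tolerance > 0, lambda >= 0,
            beta >= 0, min_size_per_species >= 0, exhaustive_cap >= 1)
  structure(list(m = as.integer(m), restart = restart, tolerance = tolerance,
                 lambda = lambda, beta = beta,
                 min_size_per_species = as.integer(min_size_per_species),
                 exhaustive_cap = as.integer(exhaustive_cap),
                 solver = solver, seed = as.integer(seed)),
            class = "clusterm_config")
}

#' Build a complex candidate from per-network protein sets
#'
#' Collects the induced interactions of each set and the cross-network
#' similarity pairs with both endpoints inside the candidate. Proteins are
#' namespaced by network, so identical identifiers in different species do
#' not collide.
#'
#' @param collection a `network_collection`.
#' @param sim a `similarity_map`.
#' @param sets list of k character vectors (one per network), e.g. the
#'   `members` of per-network `min_conductance_set`s.
#' @param lambda homology weight.
#' @param spine optional originating spine.
#' @return object of class `complex_candidate`.
#' @export
complex_candidate <- function(collection, sim, sets, lambda, spine = NULL) {
  k <- collection$k
  stopifnot(length(sets) == k)
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  net_of <- rep(seq_len(k), lengths(sets))
  protein <- unlist(sets, use.names = FALSE)
  id_of <- function(j, p) match(paste(j, p), paste(net_of, protein))
  edges <- matrix(integer(), ncol = 2)
  for (j in seq_len(k)) {
    if (!length(sets[[j]])) next
    sub <- igraph::induced_subgraph(collection$networks[[j]]$graph, sets[[j]])
    el <- igraph::as_edgelist(sub, names = TRUE)
    if (nrow(el)) {
      edges <- rbind(edges, cbind(id_of(j, el[, 1]), id_of(j, el[, 2])))
    }
  }
  pairs <- matrix(integer(), ncol = 2)
  pair_scores <- numeric(0)
  for (j in seq_len(k - 1L)) {
    for (l in seq((j + 1L), k)) {
      tab <- sim_between(sim, j, l)
      if (!nrow(tab)) next
      keep <- tab$p %in% sets[[j]] & tab$q %in% sets[[l]]
      tab <- tab[keep, , drop = FALSE]
      if (nrow(tab)) {
        pairs <- rbind(pairs, cbind(id_of(j, tab$p), id_of(l, tab$q)))
        pair_scores <- c(pair_scores, tab$score)
      }
    }
  }
  structure(list(sets = sets, net_of = net_of, protein = protein,
                 n_total = length(protein), edges = edges,
                 pairs = pairs, pair_scores = pair_scores,
                 lambda = lambda, spine = spine,
                 selection = rep(TRUE, length(protein))),
            class = "complex_candidate")
}

#' @export
print.complex_candidate <- function(x, ...) {
  cat(sprintf("<complex_candidate: %d proteins in %d networks, %d edges, %d homology pairs>\n",
              x$n_total, length(x$sets), nrow(x$edges), nrow(x$pairs)))
  invisible(x)
}

#' Cost of a candidate selection
#'
#' \deqn{F = -\Big(\sum_j \frac{\sum_{a,b} A^{(j)}(a,b)\delta_a\delta_b}{\sum_c \delta_c}
#'   + \lambda \frac{\sum_{j \ne l}\sum_{a,b} s(a,b)\delta_a\delta_b}{\sum_j \sum_c \delta_c}\Big)}
#' The adjacency and similarity sums run over ordered pairs, so a network's
#' density term equals twice its selected-edge count divided by its selected
#' size, and each unordered homology pair counts twice. A network with no
#' selected protein contributes 0 to the density sum; an entirely empty
#' selection has cost 0. Lower (more negative) is better.
#'
#' @param candidate a `complex_candidate`.
#' @param selection logical vector over the candidate's proteins; defaults
#'   to the candidate's current selection.
#' @return the cost value.
#' @export
complex_cost <- function(candidate, selection = candidate$selection) {
  stopifnot(length(selection) == candidate$n_total)
  n_total <- sum(selection)
  if (n_total == 0) return(0)
  dens <- 0
  for (j in seq_along(candidate$sets)) {
    nj <- sum(selection[candidate$net_of == j])
    if (nj == 0) next
    if (nrow(candidate$edges)) {
      both <- selection[candidate$edges[, 1]] & selection[candidate$edges[, 2]]
      same_net <- candidate$net_of[candidate$edges[, 1]] == j
      ej <- sum(both & same_net)
    } else ej <- 0
    dens <- dens + 2 * ej / nj
  }
  hom <- 0
  if (nrow(candidate$pairs)) {
    both <- selection[candidate$pairs[, 1]] & selection[candidate$pairs[, 2]]
    hom <- 2 * sum(candidate$pair_scores[both])
  }
  -(dens + candidate$lambda * hom / n_total)
}

#' Greedily prune a candidate to a conserved complex
#'
#' Starts from the full selection and repeatedly removes the single protein
#' whose removal lowers the cost the most (steepest descent), stopping when
#' no single removal strictly lowers it. Removal ties are broken by network
#' index, then protein identifier. Uses O(1) incremental cost updates per
#' candidate removal, so a full prune costs O((km)^2).
#'
#' @param candidate a `complex_candidate`.
#' @param trace if `TRUE`, attach the cost trace (attribute `"trace"`,
#'   strictly decreasing) to the result.
#' @return a `conserved_complex`.
#' @export
greedy_prune <- function(candidate, trace = FALSE) {
  k <- length(candidate$sets)
  N <- candidate$n_total
  sel <- rep(TRUE, N)
  net_of <- candidate$net_of
  lambda <- candidate$lambda
  # incident lists for incremental updates
  nbr <- vector("list", N); for (i in seq_len(N)) nbr[[i]] <- integer(0)
  if (nrow(candidate$edges)) {
    for (r in seq_len(nrow(candidate$edges))) {
      a <- candidate$edges[r, 1]; b <- candidate$edges[r, 2]
      nbr[[a]] <- c(nbr[[a]], b); nbr[[b]] <- c(nbr[[b]], a)
    }
  }
  prt <- vector("list", N); for (i in seq_len(N)) prt[[i]] <- integer(0)
  prt_s <- vector("list", N); for (i in seq_len(N)) prt_s[[i]] <- numeric(0)
  if (nrow(candidate$pairs)) {
    for (r in seq_len(nrow(candidate$pairs))) {
      a <- candidate$pairs[r, 1]; b <- candidate$pairs[r, 2]
      s <- candidate$pair_scores[r]
      prt[[a]] <- c(prt[[a]], b); prt_s[[a]] <- c(prt_s[[a]], s)
      prt[[b]] <- c(prt[[b]], a); prt_s[[b]] <- c(prt_s[[b]], s)
    }
  }
  n_j <- tabulate(net_of, nbins = k)
  e_j <- numeric(k)
  if (nrow(candidate$edges)) {
    te <- tabulate(net_of[candidate$edges[, 1]], nbins = k)
    e_j <- te
  }
  sdeg <- vapply(nbr, length, 1L)          # selected neighbors per protein
  ssum <- vapply(prt_s, sum, 0)            # selected similarity mass per protein
  H <- sum(candidate$pair_scores)          # unordered selected similarity sum
  Ntot <- N
  cost_now <- function() {
    d <- 0
    for (j in seq_len(k)) if (n_j[j] > 0) d <- d + 2 * e_j[j] / n_j[j]
    if (Ntot == 0) 0 else -(d + lambda * 2 * H / Ntot)
  }
  F_cur <- cost_now()
  tr <- F_cur
  # protein visit order for deterministic tie-breaks
  ord <- order(net_of, candidate$protein, method = "radix")
  eps <- 1e-12
  repeat {
    best_F <- Inf; best_i <- NA_integer_
    dens_base <- 0
    for (j in seq_len(k)) if (n_j[j] > 0) dens_base <- dens_base + 2 * e_j[j] / n_j[j]
    for (i in ord) {
      if (!sel[i]) next
      j <- net_of[i]
      dj_old <- if (n_j[j] > 0) 2 * e_j[j] / n_j[j] else 0
      nj_new <- n_j[j] - 1L
      dj_new <- if (nj_new > 0) 2 * (e_j[j] - sdeg[i]) / nj_new else 0
      d_new <- dens_base - dj_old + dj_new
      H_new <- H - ssum[i]
      Nt <- Ntot - 1L
      F_i <- if (Nt == 0) 0 else -(d_new + lambda * 2 * H_new / Nt)
      if (F_i < best_F - eps) { best_F <- F_i; best_i <- i }
    }
    if (is.na(best_i) || best_F >= F_cur - eps) break
    i <- best_i; j <- net_of[i]
    sel[i] <- FALSE
    n_j[j] <- n_j[j] - 1L
    e_j[j] <- e_j[j] - sdeg[i]
    H <- H - ssum[i]
    Ntot <- Ntot - 1L
    for (v in nbr[[i]]) if (sel[v]) sdeg[v] <- sdeg[v] - 1L
    if (length(prt[[i]])) {
      for (r in seq_along(prt[[i]])) {
        v <- prt[[i]][r]
        if (sel[v]) ssum[v] <- ssum[v] - prt_s[[i]][r]
      }
    }
    # neighbors' sdeg/ssum only count selected partners: recompute lazily by
    # subtracting contributions of i (done above); i's own entries now inert
    F_cur <- best_F
    tr <- c(tr, F_cur)
  }
  sets <- lapply(seq_len(k), function(j) {
    candidate$protein[sel & net_of == j]
  })
  out <- conserved_complex(sets, spine = candidate$spine, cost = F_cur,
                           internal_similarity = H)
  if (trace) attr(out, "trace") <- tr
  out
}

#' Post-process a list of conserved complexes
#'
#' Three filters, in order: (1) exact duplicates (all k protein sets equal)
#' are removed, keeping the first occurrence; (2) complexes whose internal
#' similarity sum is below `beta` are dropped; (3) if
#' `min_size_per_species > 0`, complexes with fewer proteins than that in
#' any species are dropped.
#'
#' @param complexes list of `conserved_complex`.
#' @param beta similarity-sum threshold (default 0.1).
#' @param min_size_per_species per-species minimum size (0 disables).
#' @return filtered list.
#' @export
postprocess <- function(complexes, beta = 0.1, min_size_per_species = 0L) {
  if (!length(complexes)) return(complexes)
  sigs <- vapply(complexes, complex_signature, "")
  complexes <- complexes[!duplicated(sigs)]
  keep <- vapply(complexes, function(cx) {
    isTRUE(cx$internal_similarity >= beta)
  }, TRUE)
  complexes <- complexes[keep]
  if (min_size_per_species > 0L) {
    keep <- vapply(complexes, function(cx) {
      all(vapply(cx$sets, length, 1L) >= min_size_per_species)
    }, TRUE)
    complexes <- complexes[keep]
  }
  complexes
}

run_one_spine <- function(collection, sim, spine, config) {
  k <- collection$k
  sets <- vector("list", k)
  for (j in seq_len(k)) {
    net <- collection$networks[[j]]
    pr <- personalized_pagerank(net, spine[j], restart = config$restart,
                                tolerance = config$tolerance)
    nb <- top_m_neighborhood(net, spine[j], pr, m = config$m, network_index = j)
    mcs <- min_conductance_subset(net, nb, mode = config$solver,
                                  exhaustive_cap = config$exhaustive_cap)
    sets[[j]] <- mcs$members
  }
  cand <- complex_candidate(collection, sim, sets, lambda = config$lambda,
                            spine = spine)
  greedy_prune(cand)
}

#' Run the full conserved-complex pipeline
#'
#' For every spine: per-network PageRank neighborhood, exact
#' minimum-conductance refinement, candidate assembly, greedy pruning; then
#' global post-processing (duplicate removal, similarity-sum filter, minimum
#' per-species size) and a canonical sort. Spines are independent, so the
#' result is invariant to their processing order and to the number of
#' workers.
#'
#' @param collection a `network_collection`.
#' @param sim a `similarity_map`.
#' @param spines a `spine_set`.
#' @param config a [clusterm_config()].
#' @param workers number of parallel workers (forked; results identical for
#'   any value).
#' @return list of `conserved_complex`, canonically ordered.
#' @export
run_clusterm <- function(collection, sim, spines, config = clusterm_config(),
                         workers = 1L) {
  h <- spines$h
  if (h == 0L) return(list())
  worker <- function(i) {
    tryCatch(run_one_spine(collection, sim, spines$members[i, ], config),
             error = function(e) {
               warning(sprintf("spine %d skipped: %s", i, conditionMessage(e)))
               NULL
             })
  }
  results <- if (workers > 1L) {
    parallel::mclapply(seq_len(h), worker, mc.cores = workers)
  } else {
    lapply(seq_len(h), worker)
  }
  results <- Filter(Negate(is.null), results)
  out <- postprocess(results, beta = config$beta,
                     min_size_per_species = config$min_size_per_species)
  out <- out[order(vapply(out, complex_signature, ""))]
  attr(out, "stats") <- list(spines = h, complexes_raw = length(results),
                             complexes_final = length(out))
  out
}
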