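# Task 1: local topological separation. For each spine protein we rank its
# surroundings with an approximate personalized PageRank vector, keep the top
# m proteins as the working neighborhood H, and extract the exact
# minimum-conductance seed-containing subset of H. Conductance is measured
# against the host network: phi(S) = |E(S, V\S)| / vol(S) with vol(S) the sum
# of full-network degrees, the small-set simplification of the usual
# min-volume definition. Restricting the candidate sets to subsets of H is
# what makes the optimization local and the whole algorithm scale.

.pkg_cache <- new.env(parent = emptyenv())

popcount16 <- function() {
  pc <- get0("pc16", envir = .pkg_cache)
  if (is.null(pc)) {
    pc <- integer(65536L)
    for (i in 1:65535) pc[i + 1L] <- pc[i %/% 2L + 1L] + i %% 2L
    assign("pc16", pc, envir = .pkg_cache)
  }
  pc
}

popcount <- function(x) {
  pc <- popcount16()
  pc[bitwAnd(x, 65535L) + 1L] + pc[bitwShiftR(x, 16L) + 1L]
}

#' Approximate personalized PageRank by local push
#'
#' Random walk with restart to a fixed seed, approximated with the local
#' push scheme: mass is propagated from a residual vector until the residual
#' at every node is below `tolerance` times its degree, so the cost is
#' proportional to the size of the visited neighborhood rather than the
#' network.
#'
#' @param network a `ppi_network`.
#' @param seed seed protein (must be in the network).
#' @param restart restart probability in (0,1); default 0.15.
#' @param tolerance residual tolerance per unit degree; default 1e-4.
#' @return named numeric vector of PageRank scores over the visited nodes
#'   (non-negative, summing to at most 1). An isolated seed gets unit mass.
#' @export
personalized_pagerank <- function(network, seed, restart = 0.15,
                                  tolerance = 1e-4) {
  stopifnot(restart > 0, restart < 1, tolerance > 0)
  g <- network$graph
  vnames <- igraph::V(g)$name
  s <- match(seed, vnames)
  if (is.na(s)) stop(sprintf("seed protein '%s' not in network '%s'", seed,
                             network$species))
  deg <- igraph::degree(g)
  if (deg[s] == 0) return(setNames(1, seed))
  adj <- igraph::as_adj_list(g, mode = "all")
  n <- length(vnames)
  p <- numeric(n)
  r <- numeric(n)
  r[s] <- 1
  queue <- s
  inq <- logical(n)
  inq[s] <- TRUE
  while (length(queue)) {
    u <- queue[[1]]
    queue <- queue[-1]
    inq[u] <- FALSE
    ru <- r[u]
    if (ru < tolerance * deg[u]) next
    p[u] <- p[u] + restart * ru
    r[u] <- 0
    nb <- as.integer(adj[[u]])
    share <- (1 - restart) * ru / deg[u]
    r[nb] <- r[nb] + share
    push <- nb[r[nb] >= tolerance * deg[nb] & !inq[nb] & deg[nb] > 0]
    if (length(push)) {
      inq[push] <- TRUE
      queue <- c(queue, push)
    }
  }
  pos <- p > 0
  setNames(p[pos], vnames[pos])
}

#' Top-m PageRank neighborhood
#'
#' The seed plus the m-1 highest-scoring other proteins; score ties are
#' broken by higher degree, then lexicographic identifier. If fewer than m
#' proteins have positive score, all of them are returned.
#'
#' @param network a `ppi_network`.
#' @param seed seed protein.
#' @param scores output of [personalized_pagerank()].
#' @param m neighborhood size (>= 1).
#' @param network_index optional index of the host network in its collection.
#' @return object of class `ppr_neighborhood` with fields `seed`, `members`
#'   (sorted, seed included), `scores`, `network_index`.
#' @export
top_m_neighborhood <- function(network, seed, scores, m, network_index = NA_integer_) {
  stopifnot(m >= 1)
  cand <- setdiff(names(scores)[scores > 0], seed)
  deg <- net_degree(network)
  ord <- order(-scores[cand], -deg[cand], cand, method = "radix")
  members <- c(seed, cand[ord][seq_len(min(m - 1L, length(cand)))])
  structure(list(seed = seed, members = sort(members),
                 scores = scores[intersect(names(scores), members)],
                 network_index = network_index),
            class = "ppr_neighborhood")
}

#' Conductance of a protein set
#'
#' \deqn{\phi(S) = |E(S,\bar S)| / vol(S)} with \eqn{vol(S)} the sum of the
#' members' degrees in `network`. A zero-volume set has conductance 1 by
#' convention. With `strict = TRUE` the denominator is
#' \eqn{\min\{vol(S), vol(\bar S)\}}, the unsimplified definition.
#'
#' @param network a `ppi_network`.
#' @param subset non-empty character vector of member proteins.
#' @param strict use the min-volume denominator (default `FALSE`).
#' @return conductance value (in `[0,1]` whenever `vol(S) <= vol(S-bar)`).
#' @export
conductance <- function(network, subset, strict = FALSE) {
  subset <- unique(subset)
  if (length(subset) == 0) stop("subset must be non-empty")
  vn <- net_proteins(network)
  if (!all(subset %in% vn)) stop("subset contains proteins not in the network")
  deg <- net_degree(network)
  vol <- sum(deg[subset])
  e_in <- igraph::ecount(igraph::induced_subgraph(network$graph, subset))
  cut <- vol - 2 * e_in
  denom <- if (strict) min(vol, sum(deg) - vol) else vol
  if (denom == 0) return(1)
  cut / denom
}

# Internal instance shared by both solver modes: member names, seed index,
# host degrees, and the induced adjacency as index lists.
mcs_instance <- function(network, neighborhood, degrees = "host") {
  members <- sort(unique(neighborhood$members))
  seed <- neighborhood$seed
  if (!(seed %in% members)) stop("neighborhood must contain its seed")
  sub <- igraph::induced_subgraph(network$graph, members)
  sub_names <- igraph::V(sub)$name
  el <- igraph::as_edgelist(sub, names = FALSE)
  n <- length(sub_names)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(el)) {
    for (r in seq_len(nrow(el))) {
      a <- el[r, 1]; b <- el[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  deg_h <- vapply(adj, length, 1L)
  d <- if (degrees == "induced") deg_h else
    as.integer(net_degree(network, sub_names))
  list(names = sub_names, n = n, seed_i = match(seed, sub_names),
       edges = el, adj = adj, deg_host = d, deg_h = deg_h)
}

mcs_result <- function(inst, sel_idx, value, neighborhood, mode) {
  structure(list(network_index = neighborhood$network_index,
                 seed = neighborhood$seed,
                 members = sort(inst$names[sel_idx]),
                 conductance_value = value,
                 mode = mode),
            class = "min_conductance_set")
}

#' @export
print.min_conductance_set <- function(x, ...) {
  cat(sprintf("<min_conductance_set: seed '%s', %d proteins, phi = %.6g (%s)>\n",
              x$seed, length(x$members), x$conductance_value, x$mode))
  invisible(x)
}

# Exhaustive enumeration over all seed-containing subsets, vectorized over
# bitmasks. Serves as the oracle for the parametric solver.
mcs_exhaustive <- function(inst) {
  n <- inst$n
  if (n > 24L) stop("exhaustive mode limited to neighborhoods of at most 24 proteins")
  bit <- as.integer(2^(seq_len(n) - 1L))
  adj_mask <- vapply(seq_len(n), function(i) {
    if (length(inst$adj[[i]])) Reduce(bitwOr, bit[inst$adj[[i]]]) else 0L
  }, 0L)
  free <- setdiff(seq_len(n), inst$seed_i)
  nf <- length(free)
  masks_free <- 0:(2^nf - 1)
  # expand free-bit masks onto the n-bit space
  masks <- rep.int(bit[inst$seed_i], length(masks_free))
  for (b in seq_len(nf)) {
    on <- bitwAnd(masks_free, as.integer(2^(b - 1L))) != 0L
    masks[on] <- masks[on] + bit[free[b]]
  }
  vol <- numeric(length(masks))
  int2 <- numeric(length(masks))
  for (i in seq_len(n)) {
    in_s <- bitwAnd(masks, bit[i]) != 0L
    vol <- vol + inst$deg_host[i] * in_s
    cnt <- popcount(bitwAnd(masks, adj_mask[i]))
    int2 <- int2 + cnt * in_s
  }
  cut <- vol - int2
  phi <- ifelse(vol > 0, cut / vol, 1)
  best <- min(phi)
  tied <- which(phi <= best + 1e-12)
  if (length(tied) > 1L) {
    sizes <- popcount(masks[tied])
    tied <- tied[sizes == max(sizes)]
    if (length(tied) > 1L) {
      reps <- vapply(tied, function(t) {
        paste(inst$names[bitwAnd(masks[t], bit) != 0L], collapse = ",")
      }, "")
      tied <- tied[order(reps)][1]
    }
  }
  pick <- tied[1]
  sel <- which(bitwAnd(masks[pick], bit) != 0L)
  list(sel = sel, value = phi[pick])
}

# One parametric subproblem: minimize q*cut(S) - p*vol(S) over seed-containing
# S, reduced to an s-t minimum cut (the quadratic pseudo-Boolean energy is
# submodular because every pairwise coefficient is negative).
mcs_parametric_cut <- function(inst, p, q) {
  n <- inst$n
  ci <- (q - p) * inst$deg_host - q * inst$deg_h
  src <- n + 1L
  snk <- n + 2L
  from <- integer(0); to <- integer(0); cap <- numeric(0)
  pos <- which(ci > 0)
  if (length(pos)) {
    from <- c(from, pos); to <- c(to, rep(snk, length(pos))); cap <- c(cap, ci[pos])
  }
  neg <- which(ci < 0)
  if (length(neg)) {
    from <- c(from, rep(src, length(neg))); to <- c(to, neg); cap <- c(cap, -ci[neg])
  }
  if (nrow(inst$edges)) {
    a <- inst$edges[, 1]; b <- inst$edges[, 2]
    from <- c(from, a, b); to <- c(to, b, a); cap <- c(cap, rep(q, 2 * length(a)))
  }
  big <- sum(cap) + 1
  from <- c(from, src); to <- c(to, inst$seed_i); cap <- c(cap, big)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  if (igraph::vcount(g) < snk) g <- igraph::add_vertices(g, snk - igraph::vcount(g))
  mf <- igraph::max_flow(g, source = src, target = snk, capacity = cap)
  sel <- setdiff(as.integer(mf$partition1), c(src, snk))
  sel <- sel[sel <= n]
  sel
}

mcs_energy <- function(inst, sel) {
  vol <- sum(inst$deg_host[sel])
  in_s <- logical(inst$n); in_s[sel] <- TRUE
  e_in <- if (nrow(inst$edges))
    sum(in_s[inst$edges[, 1]] & in_s[inst$edges[, 2]]) else 0L
  list(cut = vol - 2 * e_in, vol = vol)
}

# Exact minimization of the binary fractional program by Dinkelbach's
# parametric method: repeatedly solve min q*cut - p*vol at lambda = p/q until
# the parametric optimum is zero, at which point lambda is the minimum
# conductance. All arithmetic on cut/vol is integer, so termination is exact.
mcs_exact <- function(inst, max_iter = 100L) {
  seed_i <- inst$seed_i
  e0 <- mcs_energy(inst, seed_i)
  if (e0$vol == 0) return(list(sel = seed_i, value = 1))
  best_sel <- seed_i
  p <- e0$cut; q <- e0$vol
  g <- gcd_int(p, q); p <- p / g; q <- q / g
  if (p == 0) return(list(sel = best_sel, value = 0))
  for (iter in seq_len(max_iter)) {
    sel <- mcs_parametric_cut(inst, p, q)
    if (!(seed_i %in% sel) || length(sel) == 0L) sel <- best_sel
    e <- mcs_energy(inst, sel)
    gval <- q * e$cut - p * e$vol
    if (gval >= 0 || e$vol == 0) {
      return(list(sel = best_sel, value = p / q))
    }
    best_sel <- sel
    p <- e$cut; q <- e$vol
    g <- gcd_int(p, q); if (g > 0) { p <- p / g; q <- q / g }
    if (p == 0) return(list(sel = best_sel, value = 0))
  }
  NULL  # did not converge; caller falls back
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  max(a, 1)
}

# Sweep cut over PageRank order: last-resort fallback.
mcs_sweep <- function(inst, neighborhood) {
  sc <- neighborhood$scores
  ord_names <- names(sort(sc, decreasing = TRUE))
  ord_names <- unique(c(neighborhood$seed, ord_names))
  idx <- match(ord_names, inst$names)
  idx <- idx[!is.na(idx)]
  best <- NULL; best_phi <- Inf
  for (t in seq_along(idx)) {
    sel <- idx[seq_len(t)]
    e <- mcs_energy(inst, sel)
    phi <- if (e$vol > 0) e$cut / e$vol else 1
    if (phi < best_phi) { best_phi <- phi; best <- sel }
  }
  list(sel = best, value = best_phi)
}

#' Exact minimum-conductance subset of a neighborhood
#'
#' Solves \deqn{\min_{S \ni seed,\ S \subseteq H} \phi(S)} exactly. The
#' objective is the binary fractional program
#' \eqn{x^T (D - A^H) x / x^T D x} over indicator vectors with the seed
#' fixed to 1, where \eqn{A^H} is the adjacency of the subnetwork induced by
#' the neighborhood and \eqn{D} carries the members' host-network degrees,
#' making the numerator the boundary-edge count of the selection in the full
#' network.
#'
#' Mode `"exact"` (alias `"mip"`) solves the program exactly with
#' Dinkelbach's parametric method, each parametric subproblem reduced to an
#' s-t minimum cut; mode `"exhaustive"` enumerates all seed-containing
#' subsets and applies the canonical tie-break (larger set, then
#' lexicographically smallest member list). Both return the same minimal
#' conductance; the chosen subset can differ only among exact ties. If the
#' parametric solver fails to converge the function falls back to
#' exhaustive enumeration when the neighborhood has at most `exhaustive_cap`
#' members and otherwise to the best sweep cut over PageRank order, with a
#' warning.
#'
#' @param network the host `ppi_network`.
#' @param neighborhood a `ppr_neighborhood`.
#' @param mode `"exact"`, `"mip"` or `"exhaustive"`.
#' @param exhaustive_cap largest neighborhood enumerated on fallback
#'   (default 15).
#' @param degrees `"host"` (default) measures separation from the full
#'   network; `"induced"` uses degrees of the induced subnetwork only (kept
#'   for completeness; degenerate, since any union of components of H then
#'   scores 0).
#' @return object of class `min_conductance_set` with fields `seed`,
#'   `members`, `conductance_value`, `mode`.
#' @export
min_conductance_subset <- function(network, neighborhood,
                                   mode = c("exact", "mip", "exhaustive"),
                                   exhaustive_cap = 15L,
                                   degrees = c("host", "induced")) {
  mode <- match.arg(mode)
  degrees <- match.arg(degrees)
  inst <- mcs_instance(network, neighborhood, degrees = degrees)
  if (inst$n == 1L) {
    return(mcs_result(inst, 1L, if (inst$deg_host[1] > 0) 1 else 1,
                      neighborhood, mode))
  }
  if (mode == "exhaustive") {
    res <- mcs_exhaustive(inst)
  } else {
    res <- mcs_exact(inst)
    if (is.null(res)) {
      if (inst$n <= exhaustive_cap) {
        warning("parametric solver did not converge; falling back to exhaustive enumeration")
        res <- mcs_exhaustive(inst)
      } else {
        warning("parametric solver did not converge; falling back to sweep cut")
        res <- mcs_sweep(inst, neighborhood)
      }
    }
    mode <- "exact"
  }
  mcs_result(inst, res$sel, res$value, neighborhood, mode)
}
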