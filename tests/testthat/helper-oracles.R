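# Shared fixture builders and independent oracles used across the suite.

path5 <- function() {
  ppi_network(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e")), "path")
}

triangle_net <- function(p, species = "tri") {
  ppi_network(rbind(c(p[1], p[2]), c(p[1], p[3]), c(p[2], p[3])), species)
}

# two triangles {a,b,c}, {d,e,f} bridged by c-d
bridge_net <- function() {
  ppi_network(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                    c("d", "e"), c("d", "f"), c("e", "f"),
                    c("c", "d")), "bridge")
}

random_net <- function(n, p, species = "rnd") {
  g <- igraph::sample_gnp(n, p)
  nm <- sprintf("v%03d", seq_len(n))
  igraph::V(g)$name <- nm
  ppi_network(igraph::as_edgelist(g), species, proteins = nm)
}

# dense linear-system personalized PageRank: p = a (I - (1-a) W')^{-1} e_s
ppr_dense <- function(network, seed, restart = 0.15) {
  g <- network$graph
  nm <- igraph::V(g)$name
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  d <- rowSums(A)
  W <- A / ifelse(d > 0, d, 1)
  n <- length(nm)
  e <- numeric(n); e[match(seed, nm)] <- 1
  p <- solve(diag(n) - (1 - restart) * t(W), restart * e)
  setNames(as.numeric(p), nm)
}

# exhaustive minimizer of the candidate cost over all selections
exhaustive_min_cost <- function(candidate) {
  n <- candidate$n_total
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    f <- complex_cost(candidate, sel)
    if (f < best) best <- f
  }
  best
}

# brute-force maximum-weight one-to-one assignment on a weight matrix
brute_force_matching <- function(B) {
  n <- nrow(B); m <- ncol(B)
  best <- 0
  rec <- function(j, used, acc) {
    if (j > n) { best <<- max(best, acc); return(invisible()) }
    rec(j + 1L, used, acc)  # leave reference j unmatched
    for (i in seq_len(m)) {
      if (!used[i] && B[j, i] > 0) {
        used[i] <- TRUE
        rec(j + 1L, used, acc + B[j, i])
        used[i] <- FALSE
      }
    }
  }
  rec(1L, logical(m), 0)
  best
}

# small two-triangle conserved-complex fixture with perfect orthology
two_triangle_world <- function(lambda = 1) {
  n1 <- triangle_net(c("a1", "b1", "c1"), "s1")
  n2 <- triangle_net(c("a2", "b2", "c2"), "s2")
  coll <- network_collection(list(n1, n2))
  tab <- data.frame(p = c("a1", "b1", "c1"), q = c("a2", "b2", "c2"), score = 1)
  sim <- similarity_map(list(list(net_i = 1, net_j = 2, table = tab)), coll)
  cand <- complex_candidate(coll, sim, list(c("a1", "b1", "c1"),
                                            c("a2", "b2", "c2")), lambda = lambda)
  list(collection = coll, sim = sim, candidate = cand)
}

ref <- function(s1, s2) reference_pair(s1, s2)
cxp <- function(s1, s2) conserved_complex(list(s1, s2))
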