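# Spine seeding: either load the output of an external multiple network
# aligner (read_spines) or build spines internally from reciprocal best
# similarity hits. The internal builder is deliberately simple and
# deterministic; many-to-many homology still enters downstream through the
# cost function, so the one-to-one restriction here only concerns seeding.

#' Build protein spines from reciprocal best similarity hits
#'
#' Deterministic greedy chaining: proteins of network 1 are visited in
#' lexicographic order; from each, the chain is extended through networks
#' 2..k by taking the highest-similarity partner not yet used in any spine,
#' requiring a reciprocal best hit at each hop (the chosen partner's best
#' partner in the previous network must be the chaining protein). A spine is
#' emitted only if all k slots fill; each protein enters at most one spine.
#' Ties are broken lexicographically by protein identifier.
#'
#' @param collection a `network_collection`.
#' @param sim a `similarity_map` covering all consecutive network pairs.
#' @param max_spines optional cap on the number of spines (default
#'   unlimited).
#' @return a `spine_set` (possibly empty).
#' @export
build_spines <- function(collection, sim, max_spines = Inf) {
  k <- collection$k
  # per consecutive pair, best-partner tables in both directions
  fwd <- vector("list", k - 1L)  # j -> j+1: for each p, partners sorted by score
  best_back <- vector("list", k - 1L)  # j -> j+1: for each q, its best p
  for (j in seq_len(k - 1L)) {
    tab <- sim_between(sim, j, j + 1L)
    # sort by p, score desc, partner asc for deterministic preference order
    ord <- order(tab$p, -tab$score, tab$q, method = "radix")
    fwd[[j]] <- split(tab[ord, c("q", "score")], tab$p[ord])
    ordb <- order(tab$q, -tab$score, tab$p, method = "radix")
    tb <- tab[ordb, , drop = FALSE]
    first <- !duplicated(tb$q)
    best_back[[j]] <- setNames(tb$p[first], tb$q[first])
  }
  used <- lapply(seq_len(k), function(j) new.env(parent = emptyenv()))
  spines <- list()
  for (p in sort(net_proteins(collection$networks[[1]]))) {
    if (length(spines) >= max_spines) break
    if (!is.null(get0(p, envir = used[[1]]))) next
    chain <- p
    ok <- TRUE
    for (j in seq_len(k - 1L)) {
      cur <- chain[j]
      cands <- fwd[[j]][[cur]]
      q <- NULL
      if (!is.null(cands)) {
        for (r in seq_len(nrow(cands))) {
          cand <- cands$q[r]
          if (!is.null(get0(cand, envir = used[[j + 1L]]))) next
          # reciprocal best-hit: cand's best partner in network j must be cur
          if (identical(unname(best_back[[j]][cand]), cur)) q <- cand
          break  # only the top unused candidate is considered
        }
      }
      if (is.null(q)) { ok <- FALSE; break }
      chain <- c(chain, q)
    }
    if (ok) {
      for (j in seq_len(k)) assign(chain[j], TRUE, envir = used[[j]])
      spines[[length(spines) + 1L]] <- chain
    }
  }
  members <- if (length(spines)) do.call(rbind, spines) else
    matrix(character(), ncol = k)
  spine_set(members, collection)
}
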