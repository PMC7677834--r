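# Planted-complex benchmark generator. Each of k networks carries the same
# set of planted modules (dense, mutually disjoint, connected) embedded in an
# Erdos-Renyi background; counterpart modules across networks are linked by
# index-matched ortholog similarities, with optional random decoy
# similarities. Ground truth (per-network member sets and one spine per
# complex) is returned alongside, so the full pipeline and every metric can
# be exercised offline.

#' Generate a planted world of conserved complexes
#'
#' Defaults are the benchmark conditions used throughout the package's own
#' evaluation: two networks, ten planted complexes of five proteins each,
#' within-module edge probability 0.9, module-background attachment
#' probability 0.02, a 200-node background with mean degree about 4.
#' Modules are resampled until internally connected (a protein complex is a
#' connected assembly; a disconnected "module" is unrecoverable by any
#' local method and would make ground truth meaningless). Ortholog
#' similarities are Normal(0.6, 0.15) clipped to `[threshold, 1]`; decoy
#' similarities are sprinkled uniformly in `[threshold, 0.3]`.
#'
#' @param k number of networks.
#' @param n_complexes number of planted conserved complexes.
#' @param size_range integer range of complex sizes (inclusive).
#' @param p_in within-module edge probability (> p_out).
#' @param p_out module-to-background attachment probability per node pair.
#' @param n_background background proteins per network.
#' @param p_background background edge probability.
#' @param ortholog_mean,ortholog_sd similarity distribution of true
#'   orthologs.
#' @param decoy_rate fraction of possible cross-network pairs given a decoy
#'   similarity.
#' @param threshold similarity threshold (as in [similarity_map()]).
#' @param seed integer seed; the world is fully determined by it.
#' @return object of class `planted_world`: fields `collection`, `sim`,
#'   `spines`, `truth` (list of per-network set lists), `params`.
#' @export
generate_planted_world <- function(k = 2L, n_complexes = 10L,
                                   size_range = c(5L, 5L),
                                   p_in = 0.9, p_out = 0.02,
                                   n_background = 200L, p_background = 0.02,
                                   ortholog_mean = 0.6, ortholog_sd = 0.15,
                                   decoy_rate = 0.001, threshold = 0.1,
                                   seed = 1L) {
  stopifnot(k >= 2, n_complexes >= 0, min(size_range) >= 3, p_in > p_out)
  set.seed(seed)
  size_pool <- seq(size_range[1], size_range[2])
  sizes <- if (n_complexes > 0) {
    if (length(size_pool) == 1L) rep(size_pool, n_complexes) else
      sample(size_pool, n_complexes, replace = TRUE)
  } else integer(0)
  species <- paste0("sp", seq_len(k))
  networks <- vector("list", k)
  truth <- lapply(seq_len(n_complexes), function(i) vector("list", k))
  module_names <- lapply(seq_len(n_complexes), function(i) {
    lapply(seq_len(k), function(j) {
      sprintf("%s_c%02d_p%02d", species[j], i, seq_len(sizes[i]))
    })
  })
  for (j in seq_len(k)) {
    bg <- sprintf("%s_bg%03d", species[j], seq_len(n_background))
    edges <- list()
    # background: Erdos-Renyi
    if (n_background >= 2 && p_background > 0) {
      pairs <- combn(bg, 2)
      on <- runif(ncol(pairs)) < p_background
      if (any(on)) edges[[length(edges) + 1L]] <- t(pairs[, on, drop = FALSE])
    }
    for (i in seq_len(n_complexes)) {
      mod <- module_names[[i]][[j]]
      truth[[i]][[j]] <- mod
      # internal edges, resampled until connected
      pairs <- combn(mod, 2)
      repeat {
        on <- runif(ncol(pairs)) < p_in
        em <- t(pairs[, on, drop = FALSE])
        g <- igraph::graph_from_data_frame(
          as.data.frame(em, stringsAsFactors = FALSE), directed = FALSE,
          vertices = data.frame(name = mod))
        if (igraph::is_connected(g)) break
      }
      edges[[length(edges) + 1L]] <- em
      # attachment to background
      if (p_out > 0 && n_background > 0) {
        att <- expand.grid(mod, bg, stringsAsFactors = FALSE)
        on <- runif(nrow(att)) < p_out
        if (any(on)) edges[[length(edges) + 1L]] <- as.matrix(att[on, , drop = FALSE])
      }
    }
    all_prot <- c(unlist(lapply(module_names, `[[`, j)), bg)
    em <- if (length(edges)) do.call(rbind, edges) else matrix(character(), ncol = 2)
    networks[[j]] <- ppi_network(em, species = species[j], proteins = all_prot)
  }
  collection <- network_collection(networks)
  # ortholog similarities: index-matched across counterpart modules
  tables <- list()
  for (j in seq_len(k - 1L)) {
    for (l in seq((j + 1L), k)) {
      rows <- list()
      for (i in seq_len(n_complexes)) {
        s <- pmin(pmax(rnorm(sizes[i], ortholog_mean, ortholog_sd), threshold), 1)
        rows[[length(rows) + 1L]] <- data.frame(
          p = module_names[[i]][[j]], q = module_names[[i]][[l]], score = s,
          stringsAsFactors = FALSE)
      }
      if (decoy_rate > 0) {
        pj <- net_proteins(networks[[j]]); pl <- net_proteins(networks[[l]])
        n_decoy <- round(decoy_rate * length(pj) * length(pl))
        if (n_decoy > 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            p = sample(pj, n_decoy, replace = TRUE),
            q = sample(pl, n_decoy, replace = TRUE),
            score = runif(n_decoy, threshold, 0.3),
            stringsAsFactors = FALSE)
        }
      }
      tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(p = character(), q = character(), score = numeric())
      tables[[length(tables) + 1L]] <- list(net_i = j, net_j = l, table = tab)
    }
  }
  sim <- similarity_map(tables, collection, threshold = threshold)
  spines <- if (n_complexes > 0) {
    spine_set(t(vapply(seq_len(n_complexes), function(i) {
      vapply(seq_len(k), function(j) module_names[[i]][[j]][1], "")
    }, character(k))), collection)
  } else {
    spine_set(matrix(character(), ncol = k), collection)
  }
  structure(list(collection = collection, sim = sim, spines = spines,
                 truth = truth,
                 params = list(k = k, n_complexes = n_complexes,
                               size_range = size_range, p_in = p_in,
                               p_out = p_out, n_background = n_background,
                               p_background = p_background,
                               ortholog_mean = ortholog_mean,
                               ortholog_sd = ortholog_sd,
                               decoy_rate = decoy_rate, threshold = threshold,
                               seed = seed)),
            class = "planted_world")
}

#' @export
print.planted_world <- function(x, ...) {
  cat(sprintf("<planted_world: k=%d, %d planted complexes, seed %d>\n",
              x$params$k, x$params$n_complexes, x$params$seed))
  invisible(x)
}

#' Project planted truth onto pairwise reference complexes
#'
#' @param world a `planted_world`.
#' @param pair which two networks to project onto. The default `NULL`
#'   projects networks 1 and 2 when k = 2 and otherwise returns a named
#'   list with one projection per network pair (choose(k, 2) of them).
#' @return list of `reference_pair`, or a named list of such lists.
#' @export
truth_as_references <- function(world, pair = NULL) {
  project <- function(pr) {
    lapply(world$truth, function(tr) reference_pair(tr[[pr[1]]], tr[[pr[2]]]))
  }
  if (!is.null(pair)) return(project(pair))
  k <- world$params$k
  if (k == 2L) return(project(c(1L, 2L)))
  prs <- combn(k, 2)
  out <- lapply(seq_len(ncol(prs)), function(c_) project(prs[, c_]))
  names(out) <- apply(prs, 2, paste, collapse = "-")
  out
}

#' Write a planted world to a fixture directory
#'
#' Emits every standard input format: per-network edge lists, a pairwise
#' similarity TSV per network pair, the spine TSV, and the truth complexes,
#' so the generated fixtures double as end-to-end command-line inputs.
#'
#' @param world a `planted_world`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_planted_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coll <- world$collection
  for (j in seq_len(coll$k)) {
    net <- coll$networks[[j]]
    path <- file.path(dir, sprintf("network_%s.tsv", net$species))
    e <- net_edges(net)
    writeLines(paste(e[, 1], e[, 2], sep = "\t"), path)
  }
  for (j in seq_len(coll$k - 1L)) {
    for (l in seq((j + 1L), coll$k)) {
      write_similarity_tsv(world$sim, coll,
                           file.path(dir, sprintf("similarity_%s_%s.tsv",
                                                  coll$species[j], coll$species[l])),
                           pair = c(j, l))
    }
  }
  write_spines(world$spines, file.path(dir, "spines.tsv"))
  write_complexes(lapply(world$truth, conserved_complex),
                  file.path(dir, "truth_complexes.tsv"))
  invisible(dir)
}
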