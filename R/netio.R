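#' @importFrom stats rnorm runif setNames sd
#' @importFrom utils read.table write.table head combn
NULL

# ---- PPI networks ------------------------------------------------------------

#' Construct a PPI network
#'
#' A PPI network is an undirected simple graph over protein identifiers:
#' no self-loops, no multi-edges, possibly with degree-0 isolates.
#'
#' @param edges two-column character matrix or data frame of interactions.
#' @param species short species tag (e.g. "Sce", "Hsa").
#' @param proteins optional character vector of proteins; defaults to the
#'   union of edge endpoints. Extra entries become isolates.
#' @return an object of class `ppi_network` wrapping an [igraph] graph.
#' @export
ppi_network <- function(edges, species, proteins = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (length(edges) == 0L) edges <- matrix(character(), ncol = 2)
  storage.mode(edges) <- "character"
  keep <- edges[, 1] != edges[, 2]
  edges <- edges[keep, , drop = FALSE]
  # canonical unordered representation, duplicates collapsed
  flip <- edges[, 1] > edges[, 2]
  edges[flip, ] <- edges[flip, c(2, 1)]
  edges <- unique(edges)
  verts <- sort(unique(c(as.vector(edges), proteins)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE)
  )
  structure(list(species = species, graph = g), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network '%s': %d proteins, %d interactions>\n",
              x$species, igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Proteins of a network
#' @param network a `ppi_network`.
#' @return character vector of protein identifiers.
#' @export
net_proteins <- function(network) igraph::V(network$graph)$name

#' Degrees of a network
#' @param network a `ppi_network`.
#' @param proteins optional subset of proteins.
#' @return named integer vector of interaction counts.
#' @export
net_degree <- function(network, proteins = NULL) {
  d <- igraph::degree(network$graph)
  if (!is.null(proteins)) d[proteins] else d
}

#' Edges of a network
#' @param network a `ppi_network`.
#' @return two-column character matrix, each unordered pair once, endpoints
#'   sorted within a row.
#' @export
net_edges <- function(network) {
  e <- igraph::as_edgelist(network$graph, names = TRUE)
  if (nrow(e)) {
    flip <- e[, 1] > e[, 2]
    e[flip, ] <- e[flip, c(2, 1)]
  }
  e
}

#' Read a PPI network from a two-column edge list
#'
#' Lines starting with `#` are ignored; fields are whitespace/tab separated.
#' Duplicate edges are collapsed and self-loop lines dropped with a warning.
#'
#' @param path path to the edge-list file.
#' @param species species tag attached to the network.
#' @return a `ppi_network`.
#' @export
read_edge_list <- function(path, species) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  parts <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed edge-list line %d in '%s': fewer than 2 columns",
                 idx[bad[1]], path))
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  n_self <- sum(a == b)
  if (n_self > 0) {
    warning(sprintf("dropped %d self-loop line(s) in '%s'", n_self, path))
  }
  ppi_network(cbind(a, b), species = species)
}

#' Bundle networks into an ordered collection
#'
#' @param networks list of `ppi_network` objects with unique species tags.
#' @return object of class `network_collection` with fields `networks`, `k`,
#'   `species`.
#' @export
network_collection <- function(networks) {
  stopifnot(length(networks) >= 2L)
  tags <- vapply(networks, function(n) n$species, "")
  if (anyDuplicated(tags)) stop("species tags must be unique")
  structure(list(networks = networks, k = length(networks), species = tags),
            class = "network_collection")
}

#' @export
print.network_collection <- function(x, ...) {
  cat(sprintf("<network_collection: k=%d [%s]>\n", x$k,
              paste(x$species, collapse = ", ")))
  invisible(x)
}

# ---- Sequence similarity -----------------------------------------------------

sim_key <- function(i, p, j, q) {
  swap <- j < i | (j == i & q < p)  # canonical orientation
  ifelse(swap, paste(j, q, i, p, sep = "\r"), paste(i, p, j, q, sep = "\r"))
}

#' Assemble a cross-network similarity map
#'
#' Stores normalized sequence-similarity scores s(p,q) in `[0,1]` for protein
#' pairs in different networks; each unordered cross pair is stored once and
#' lookups are symmetric. Scores below `threshold` are discarded, and an
#' absent pair means score 0.
#'
#' @param pair_tables list of entries `list(net_i=, net_j=, table=)` where
#'   `table` is a data frame with columns `p`, `q`, `score` (`p` in network
#'   `net_i`, `q` in network `net_j`).
#' @param collection the `network_collection` the indices refer to; entries
#'   naming unknown proteins are dropped.
#' @param threshold minimum retained score (default 0.1).
#' @return object of class `similarity_map`.
#' @export
similarity_map <- function(pair_tables, collection, threshold = 0.1) {
  rows <- list()
  for (pt in pair_tables) {
    i <- pt$net_i; j <- pt$net_j; tab <- pt$table
    stopifnot(i != j, i >= 1, j <= collection$k)
    if (i > j) {  # store with smaller index first
      tab <- data.frame(p = tab$q, q = tab$p, score = tab$score,
                        stringsAsFactors = FALSE)
      tmp <- i; i <- j; j <- tmp
    }
    known <- tab$p %in% net_proteins(collection$networks[[i]]) &
      tab$q %in% net_proteins(collection$networks[[j]])
    tab <- tab[known & tab$score >= threshold, , drop = FALSE]
    if (nrow(tab)) {
      rows[[length(rows) + 1L]] <- data.frame(
        net_i = i, net_j = j, p = tab$p, q = tab$q, score = as.numeric(tab$score),
        stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(net_i = integer(), net_j = integer(), p = character(),
               q = character(), score = numeric(), stringsAsFactors = FALSE)
  # keep max score per unordered pair
  if (nrow(entries)) {
    key <- paste(entries$net_i, entries$p, entries$net_j, entries$q, sep = "\r")
    ord <- order(key, -entries$score)
    entries <- entries[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    rownames(entries) <- NULL
  }
  if (any(entries$score > 1 + 1e-12)) stop("similarity scores must be in [0,1]")
  sim_from_entries(entries, threshold)
}

# assemble a similarity_map from a validated entries table
sim_from_entries <- function(entries, threshold) {
  rownames(entries) <- NULL
  idx <- new.env(parent = emptyenv(), size = max(29L, nrow(entries)))
  if (nrow(entries)) {
    keys <- sim_key(entries$net_i, entries$p, entries$net_j, entries$q)
    for (r in seq_len(nrow(entries))) assign(keys[r], entries$score[r], envir = idx)
  }
  structure(list(entries = entries, threshold = threshold, index = idx),
            class = "similarity_map")
}

#' @export
print.similarity_map <- function(x, ...) {
  cat(sprintf("<similarity_map: %d cross-network pairs, threshold %g>\n",
              nrow(x$entries), x$threshold))
  invisible(x)
}

#' Look up a similarity score
#'
#' Symmetric: `sim_get(sim, j, q, i, p)` equals `sim_get(sim, i, p, j, q)`.
#' Absent pairs return 0.
#'
#' @param sim a `similarity_map`.
#' @param i,j network indices.
#' @param p,q protein identifiers (vectors allowed, recycled together).
#' @return numeric vector of scores.
#' @export
sim_get <- function(sim, i, p, j, q) {
  keys <- sim_key(i, p, j, q)
  vapply(keys, function(k) {
    v <- get0(k, envir = sim$index, ifnotfound = 0)
    as.numeric(v)
  }, 0, USE.NAMES = FALSE)
}

#' Similarity entries between two networks
#' @param sim a `similarity_map`.
#' @param i,j network indices.
#' @return data frame with columns `p` (network `min(i,j)`), `q`, `score`.
#' @export
sim_between <- function(sim, i, j) {
  lo <- min(i, j); hi <- max(i, j)
  e <- sim$entries
  e[e$net_i == lo & e$net_j == hi, c("p", "q", "score"), drop = FALSE]
}

#' Normalize BLAST bit scores to similarity scores
#'
#' The similarity of proteins p and q is
#' \deqn{s(p,q) = blast(p,q) / \sqrt{blast(p,p)\, blast(q,q)},}
#' the bit score of their alignment normalized by the self-alignment bit
#' scores, so that s(p,p) = 1 and s is symmetric. When several hits exist for
#' the same pair the highest bit score is kept. Pairs with s below
#' `threshold` are discarded.
#'
#' @param hits data frame with columns `p`, `q`, `bitscore` (or any three
#'   columns in that order).
#' @param self_scores named numeric vector of self-alignment bit scores; must
#'   cover every protein occurring in `hits` and be positive.
#' @param threshold minimum retained similarity (default 0.1).
#' @return data frame with columns `p`, `q`, `score`, one row per unordered
#'   pair, suitable for [similarity_map()].
#' @export
normalize_bitscores <- function(hits, self_scores, threshold = 0.1) {
  if (!all(c("p", "q", "bitscore") %in% names(hits))) {
    names(hits)[1:3] <- c("p", "q", "bitscore")
  }
  hits$bitscore <- as.numeric(hits$bitscore)
  prots <- unique(c(hits$p, hits$q))
  missing <- setdiff(prots, names(self_scores))
  if (length(missing)) {
    stop("missing self-score for protein(s): ", paste(head(missing, 5), collapse = ", "))
  }
  if (any(self_scores[prots] <= 0)) {
    bad <- prots[self_scores[prots] <= 0][1]
    stop("non-positive self-score for protein: ", bad)
  }
  # max bit score per unordered pair
  a <- pmin(hits$p, hits$q); b <- pmax(hits$p, hits$q)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -hits$bitscore)
  first <- !duplicated(key[ord])
  a <- a[ord][first]; b <- b[ord][first]; bs <- hits$bitscore[ord][first]
  s <- bs / sqrt(self_scores[a] * self_scores[b])
  keep <- s >= threshold
  data.frame(p = a[keep], q = b[keep], score = as.numeric(s[keep]),
             stringsAsFactors = FALSE)
}

#' Read BLAST tabular hits
#'
#' Accepts outfmt-6-style tabular output (12+ columns, bit score last) or a
#' plain 3-column table `p q bitscore`.
#'
#' @param path path to the hits file.
#' @return data frame with columns `p`, `q`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BLAST tabular file needs at least 3 columns")
  data.frame(p = as.character(tab[[1]]), q = as.character(tab[[2]]),
             bitscore = as.numeric(tab[[ncol(tab)]]), stringsAsFactors = FALSE)
}

#' Read self-alignment bit scores
#'
#' Either a 2-column `protein bitscore` table, or BLAST tabular output from
#' which the rows with query equal to subject are taken.
#'
#' @param path path to the self-score file.
#' @return named numeric vector.
#' @export
read_self_scores <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 3) {
    tab <- tab[as.character(tab[[1]]) == as.character(tab[[2]]), , drop = FALSE]
    out <- setNames(as.numeric(tab[[ncol(tab)]]), as.character(tab[[1]]))
  } else {
    out <- setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
  }
  out[!duplicated(names(out))]
}

#' Read a pairwise similarity TSV
#'
#' Expected format: a header row whose first two fields are the species tags
#' of the two networks and whose third is `score`, then three columns
#' `protein_a protein_b score`.
#'
#' @param path path to the TSV.
#' @param collection `network_collection` used to resolve species tags.
#' @param threshold minimum retained score.
#' @return a `similarity_map` covering the one network pair.
#' @export
read_similarity_tsv <- function(path, collection, threshold = 0.1) {
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  i <- match(hdr[1], collection$species)
  j <- match(hdr[2], collection$species)
  if (is.na(i) || is.na(j)) {
    stop(sprintf("similarity header names unknown species: '%s', '%s'", hdr[1], hdr[2]))
  }
  tab <- read.table(path, header = FALSE, sep = "\t", skip = 1L,
                    stringsAsFactors = FALSE,
                    col.names = c("p", "q", "score"))
  similarity_map(list(list(net_i = i, net_j = j, table = tab)),
                 collection, threshold = threshold)
}

#' Write one network pair of a similarity map as TSV
#' @param sim a `similarity_map`.
#' @param collection the matching `network_collection`.
#' @param path output path.
#' @param pair integer vector of the two network indices (default `c(1, 2)`).
#' @export
write_similarity_tsv <- function(sim, collection, path, pair = c(1, 2)) {
  i <- min(pair); j <- max(pair)
  tab <- sim_between(sim, i, j)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(collection$species[i], collection$species[j], "score",
                   sep = "\t"), con)
  if (nrow(tab)) {
    writeLines(paste(tab$p, tab$q, format(tab$score, digits = 15, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

# ---- Spines ------------------------------------------------------------------

#' Construct a spine set
#'
#' A protein spine is a tuple of k proteins, one per network, used as a
#' cross-species seed. A spine set is stored as an h-by-k character matrix.
#'
#' @param members character matrix (h rows, k columns), or vector for a
#'   single spine.
#' @param collection optional `network_collection` for validation.
#' @return object of class `spine_set`.
#' @export
spine_set <- function(members, collection = NULL) {
  if (is.null(dim(members))) members <- matrix(members, nrow = 1L)
  storage.mode(members) <- "character"
  if (!is.null(collection)) {
    if (ncol(members) != collection$k) {
      stop(sprintf("spine arity %d does not match k=%d networks",
                   ncol(members), collection$k))
    }
    for (j in seq_len(ncol(members))) {
      unknown <- !(members[, j] %in% net_proteins(collection$networks[[j]]))
      if (any(unknown)) {
        r <- which(unknown)[1]
        stop(sprintf("spine row %d, column %d: protein '%s' not in network '%s'",
                     r, j, members[r, j], collection$species[j]))
      }
    }
  }
  dup <- duplicated(apply(members, 1, paste, collapse = "\r"))
  if (any(dup)) {
    warning(sprintf("dropped %d duplicated spine(s)", sum(dup)))
    members <- members[!dup, , drop = FALSE]
  }
  structure(list(members = members, h = nrow(members)), class = "spine_set")
}

#' @export
print.spine_set <- function(x, ...) {
  cat(sprintf("<spine_set: h=%d spines, k=%d networks>\n", x$h, ncol(x$members)))
  invisible(x)
}

#' Read spines from a k-column TSV
#' @param path path to the spine file.
#' @param collection `network_collection`; the column count must equal k and
#'   every protein must resolve in its network.
#' @return a `spine_set` (duplicates dropped with a warning).
#' @export
read_spines <- function(path, collection) {
  tab <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  spine_set(as.matrix(tab), collection)
}

#' Write spines as a k-column TSV
#' @param spines a `spine_set`.
#' @param path output path.
#' @export
write_spines <- function(spines, path) {
  write.table(spines$members, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- Conserved complexes -----------------------------------------------------

#' Construct a conserved complex
#'
#' @param sets list of k character vectors, the per-network protein sets.
#' @param spine optional originating spine (character vector of length k).
#' @param cost value of the topology+homology cost function at the final
#'   selection (negative is better).
#' @param internal_similarity sum of similarity scores over cross-network
#'   pairs with both endpoints in the complex (each unordered pair once).
#' @return object of class `conserved_complex`.
#' @export
conserved_complex <- function(sets, spine = NULL, cost = NA_real_,
                              internal_similarity = NA_real_) {
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  structure(list(sets = sets, spine = spine, cost = cost,
                 internal_similarity = internal_similarity),
            class = "conserved_complex")
}

#' @export
print.conserved_complex <- function(x, ...) {
  cat(sprintf("<conserved_complex: sizes [%s], cost %.4g, internal similarity %.4g>\n",
              paste(vapply(x$sets, length, 1L), collapse = "+"),
              x$cost, x$internal_similarity))
  invisible(x)
}

complex_signature <- function(cx) {
  paste(vapply(cx$sets, function(s) paste(s, collapse = ","), ""), collapse = ";")
}

#' Write conserved complexes
#'
#' One complex per line: k semicolon-separated blocks of comma-separated
#' proteins, blocks index-aligned with the species order.
#'
#' @param complexes list of `conserved_complex`.
#' @param path output path.
#' @export
write_complexes <- function(complexes, path) {
  writeLines(vapply(complexes, complex_signature, ""), path)
  invisible(path)
}

#' Read conserved complexes
#' @param path path written by [write_complexes()].
#' @return list of `conserved_complex` (costs are not serialized and read
#'   back as `NA`).
#' @export
read_complexes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    blocks <- strsplit(ln, ";", fixed = TRUE)[[1]]
    sets <- lapply(blocks, function(b) {
      v <- strsplit(b, ",", fixed = TRUE)[[1]]
      v[nzchar(v)]
    })
    conserved_complex(sets)
  })
}

# ---- GO annotations ----------------------------------------------------------

#' Construct an annotation table
#'
#' @param assignments data frame with columns `protein`, `term`, `evidence`,
#'   `aspect` (aspect is one of "P", "F", "C"); duplicates are collapsed.
#' @return object of class `annotation_table` with the assignment table plus
#'   per-term protein counts (`term_sizes`) and per-root-namespace protein
#'   counts (`root_sizes`).
#' @export
annotation_table <- function(assignments) {
  need <- c("protein", "term", "evidence", "aspect")
  stopifnot(all(need %in% names(assignments)))
  assignments <- unique(assignments[, need])
  rownames(assignments) <- NULL
  term_sizes <- tapply(assignments$protein, assignments$term,
                       function(p) length(unique(p)))
  root_sizes <- tapply(assignments$protein, assignments$aspect,
                       function(p) length(unique(p)))
  structure(list(assignments = assignments,
                 term_sizes = as.integer(term_sizes) |> setNames(names(term_sizes)),
                 root_sizes = as.integer(root_sizes) |> setNames(names(root_sizes))),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("<annotation_table: %d assignments, %d terms, %d proteins>\n",
              nrow(x$assignments), length(x$term_sizes),
              length(unique(x$assignments$protein))))
  invisible(x)
}

#' Read a GAF 2.x annotation file
#'
#' Keeps the DB object ID (column 2), GO ID (column 5), evidence code
#' (column 7) and aspect (column 9). Evidence codes are retained verbatim so
#' they can be filtered later (see [high_level_terms()]).
#'
#' @param path path to the GAF file; `!` comment lines are skipped.
#' @return an `annotation_table`.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(annotation_table(data.frame(protein = character(), term = character(),
                                       evidence = character(), aspect = character(),
                                       stringsAsFactors = FALSE)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 9L)
  if (length(bad)) stop(sprintf("GAF line %d has fewer than 9 columns", bad[1]))
  annotation_table(data.frame(
    protein = vapply(parts, `[[`, "", 2L),
    term = vapply(parts, `[[`, "", 5L),
    evidence = vapply(parts, `[[`, "", 7L),
    aspect = vapply(parts, `[[`, "", 9L),
    stringsAsFactors = FALSE))
}
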