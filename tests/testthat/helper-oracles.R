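# Independent oracles used across the suite. These deliberately take a
# different computational route from the package internals: igraph for
# spanning trees and minimax distances, exhaustive enumeration for
# bipartitions and transitive closures.

# transitive closure of "shares >= 1 allele" by exhaustive pairwise
# comparison (the brute-force sl-FFR definition)
oracle_sl_ffr <- function(ds) {
  inds <- ds$universe
  n <- length(inds)
  share <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && length(intersect(ds$genotypes[[inds[i]]],
                                  ds$genotypes[[inds[j]]])) > 0L)
      share[i, j] <- share[j, i] <- TRUE
  }
  # Warshall closure
  for (k in seq_len(n)) share <- share | (share[, k] %o% share[k, ])
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) if (comp[i] == 0L) {
    cur <- cur + 1L
    comp[share[i, ]] <- cur
  }
  partition_from_membership(inds, comp, label = ds$marker)
}

# canonical block-set signature of a partition (ignores labels/ordering)
partition_signature <- function(p) {
  sort(vapply(p$blocks, function(b) paste(sort(b), collapse = ","),
              character(1)))
}

# random diploid marker dataset over n individuals and a small allele pool
random_dataset <- function(n, n_hap = 6L, marker = "rand") {
  haps <- paste0("h", seq_len(n_hap))
  inds <- sprintf("I%02d", seq_len(n))
  genotypes <- lapply(inds, function(i) sort(sample(haps, 2L, replace = TRUE)))
  names(genotypes) <- inds
  haploweb:::.new_marker_dataset(marker, 2L, genotypes, inds)
}

random_partition <- function(n, k, label = "rp") {
  inds <- sprintf("I%02d", seq_len(n))
  grp <- c(seq_len(k), sample(k, n - k, replace = TRUE))
  partition_from_membership(inds, grp, label = label)
}

# haplotype table from bare sequences, one synthetic individual per copy
toy_table <- function(sequences, counts = NULL, marker = "toy") {
  if (is.null(counts)) counts <- rep(1L, length(sequences))
  tab <- haploweb:::.new_haplotype_table(
    marker, paste0("h", seq_along(sequences)), sequences,
    lapply(seq_along(sequences), function(i)
      sprintf("I%d_%d", i, seq_len(counts[i]))))
  tab$count <- as.integer(counts)
  tab
}

# pairwise mutation-distance matrix, via the exported single-pair API
pair_dist <- function(sequences, gap_mode = "fifth_state") {
  n <- length(sequences)
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    D[i, j] <- D[j, i] <- mutation_distance(sequences[i], sequences[j],
                                            gap_mode)$count
  D
}

# minimax ("widest path") distances by Floyd-Warshall: an edge is in the
# union of all MSTs iff its direct distance equals this minimax value
oracle_minimax <- function(D) {
  S <- D
  n <- nrow(D)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    S[i, j] <- min(S[i, j], max(S[i, k], S[k, j]))
  S
}

# MST total weight through igraph (independent of the package's Prim)
oracle_mst_cost <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(0)
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$weight)
}

# brute-force median-joining closure mirroring the documented procedure,
# built on the igraph oracles above: repeatedly scan mutually connected
# triplets of the epsilon-relaxed MSN, form majority-consensus medians
# (ties to the lowest-index member), admit those lowering the MST cost
oracle_mjn_nodes <- function(sequences, epsilon = 0L) {
  seqs <- toupper(sequences)
  repeat {
    sm <- do.call(rbind, strsplit(seqs, ""))
    D <- pair_dist(seqs)
    S <- oracle_minimax(D)
    adj <- D <= S + epsilon & D > 0
    n <- length(seqs)
    added <- FALSE
    if (n >= 3L) for (u in seq_len(n)) for (v in seq_len(n)) for (w in seq_len(n)) {
      if (!(u < v && v < w)) next
      if (!(adj[u, v] && adj[u, w] && adj[v, w])) next
      med <- vapply(seq_len(ncol(sm)), function(c) {
        st <- sort(table(sm[c(u, v, w), c]), decreasing = TRUE)
        if (st[1] >= 2L) names(st)[1] else sm[u, c]
      }, character(1))
      key <- paste(med, collapse = "")
      if (key %in% seqs) next
      # cost test is against the node set as it stands, which may already
      # include medians accepted earlier in this round
      if (oracle_mst_cost(pair_dist(c(seqs, key))) <
          oracle_mst_cost(pair_dist(seqs))) {
        seqs <- c(seqs, key)
        added <- TRUE
      }
    }
    if (!added) break
  }
  # prune degree <= 1 medians from the relaxed MSN
  n_obs <- length(sequences)
  repeat {
    D <- pair_dist(seqs)
    S <- oracle_minimax(D)
    adj <- D <= S + epsilon & D > 0
    deg <- rowSums(adj)
    drop <- which(deg <= 1L & seq_along(seqs) > n_obs)
    if (length(drop) == 0L) break
    seqs <- seqs[-drop]
  }
  sort(seqs)
}

# all spanning trees of a small complete graph, by enumerating edge subsets
oracle_all_mst_edges <- function(D) {
  n <- nrow(D)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  m <- nrow(pairs)
  best <- Inf
  in_some <- rep(FALSE, m)
  trees <- utils::combn(m, n - 1L, simplify = FALSE)
  for (tr in trees) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(pairs[tr, , drop = FALSE]))
    if (!igraph::is_connected(g)) next
    w <- sum(D[pairs[tr, , drop = FALSE]])
    if (w < best) { best <- w; in_some[] <- FALSE; in_some[tr] <- TRUE }
    else if (w == best) in_some[tr] <- TRUE
  }
  pairs[which(in_some), , drop = FALSE]
}

# simulated records written to FASTA for reader tests
write_toy_fasta <- function(ids, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}
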