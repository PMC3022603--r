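#' Haplotype network construction
#'
#' Haplonets connect observed haplotypes by edges labelled with the
#' alignment columns at which their sequences differ. Two topologies are
#' offered: the minimum-spanning network (union of all minimum spanning
#' trees of the complete mutation-distance graph) and the median-joining
#' network, which in addition inserts *median vectors* — unobserved
#' intermediate sequences hypothesised as unsampled or ancestral
#' haplotypes — wherever they lower the cost of connecting the observed
#' haplotypes. Networks serve visualisation and reporting; allele-pool
#' and FFR delineation never depends on network topology.
#'
#' @name netbuild
NULL

.seq_matrix <- function(sequences) {
  m <- do.call(rbind, strsplit(toupper(sequences), ""))
  if (is.null(m)) m <- matrix(character(0), 0, 0)
  m
}

#' Column-wise mutation distance between two aligned sequences
#'
#' @param seq_a,seq_b equal-length aligned sequences (strings).
#' @param gap_mode `"fifth_state"` treats `-` as an ordinary character
#'   state; `"ignore"` skips any column where either sequence has a gap.
#' @return list with `count` (number of differing columns) and
#'   `positions` (1-based alignment columns).
#' @examples
#' mutation_distance("AC-T", "ACTT")$count                     # 1
#' mutation_distance("AC-T", "ACTT", gap_mode = "ignore")$count # 0
#' @export
mutation_distance <- function(seq_a, seq_b,
                              gap_mode = c("fifth_state", "ignore")) {
  gap_mode <- match.arg(gap_mode)
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b))
    stop(sprintf("sequence length mismatch: %d vs %d", length(a), length(b)))
  diff <- a != b
  if (gap_mode == "ignore") diff <- diff & a != "-" & b != "-"
  pos <- which(diff)
  list(count = length(pos), positions = pos)
}

# full pairwise mutation-distance matrix over a character matrix of
# sequences (rows = haplotypes)
.dist_matrix <- function(sm, gap_mode) {
  n <- nrow(sm)
  D <- matrix(0L, n, n)
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    diff <- sm[i, ] != sm[j, ]
    if (gap_mode == "ignore") diff <- diff & sm[i, ] != "-" & sm[j, ] != "-"
    D[i, j] <- D[j, i] <- sum(diff)
  }
  D
}

# epsilon-relaxed minimum-spanning network over a distance matrix.
# sigma(u,v) = smallest d such that u and v are connected using only
# edges of length <= d; an edge belongs to the network iff its length
# <= sigma + epsilon. With epsilon = 0 this is exactly the union of all
# minimum spanning trees.
.msn_edges <- function(D, epsilon = 0L) {
  n <- nrow(D)
  if (n < 2L) return(matrix(integer(0), 0, 2))
  sigma <- matrix(NA_integer_, n, n)
  comp <- seq_len(n)
  for (t in sort(unique(D[upper.tri(D)]))) {
    newcomp <- comp
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (D[i, j] <= t && newcomp[i] != newcomp[j])
        newcomp[newcomp == newcomp[j]] <- newcomp[i]
    }
    just_connected <- outer(newcomp, newcomp, "==") &
      !outer(comp, comp, "==") & is.na(sigma)
    sigma[just_connected] <- t
    comp <- newcomp
    if (length(unique(comp)) == 1L && !anyNA(sigma[upper.tri(sigma)])) break
  }
  keep <- which(upper.tri(D) & D <= sigma + epsilon, arr.ind = TRUE)
  keep
}

# total cost of connecting all rows of D: minimum spanning tree weight
# (Prim's algorithm)
.mst_cost <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(0L)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- D[1, ]
  total <- 0L
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    total <- total + best[nxt]
    in_tree[nxt] <- TRUE
    best <- pmin(best, D[nxt, ])
  }
  total
}

.finish_network <- function(node_id, kind, hap_id, count, sequences,
                            edges, epsilon) {
  nodes <- data.frame(node_id = node_id, kind = kind, hap_id = hap_id,
                      count = count, sequence = sequences,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon),
            class = "haplonet")
}

.edges_df <- function(idx, node_id, sm, gap_mode) {
  if (nrow(idx) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      length = integer(0),
                      positions = I(list())))
  pos <- lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    diff <- sm[i, ] != sm[j, ]
    if (gap_mode == "ignore") diff <- diff & sm[i, ] != "-" & sm[j, ] != "-"
    which(diff)
  })
  data.frame(from = node_id[idx[, 1]], to = node_id[idx[, 2]],
             length = lengths(pos), positions = I(pos),
             stringsAsFactors = FALSE)
}

#' Build a minimum-spanning network
#'
#' The MSN is the union of all minimum spanning trees of the complete
#' mutation-distance graph over the observed haplotypes: an edge is kept
#' iff no path of strictly shorter edges joins its endpoints. No median
#' vectors are added.
#'
#' @param table a `haplotype_table` with sequences.
#' @param gap_mode see [mutation_distance()].
#' @param epsilon relaxation: also keep edges up to `epsilon` longer than
#'   the minimal connecting length for their endpoints. Default 0.
#' @return a `haplonet`: list with `nodes` (data.frame `node_id`, `kind`,
#'   `hap_id`, `count`, `sequence`), `edges` (data.frame `from`, `to`,
#'   `length`, list-column `positions`) and `epsilon`.
#' @export
build_msn <- function(table, gap_mode = c("fifth_state", "ignore"),
                      epsilon = 0L) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(inherits(table, "haplotype_table"), nrow(table) >= 1L)
  if (anyNA(table$sequence))
    stop("haplotype table has no sequences (label-only data); cannot build a network")
  sm <- .seq_matrix(table$sequence)
  D <- .dist_matrix(sm, gap_mode)
  idx <- .msn_edges(D, epsilon)
  .finish_network(table$hap_id, rep("observed", nrow(table)), table$hap_id,
                  table$count, table$sequence,
                  .edges_df(idx, table$hap_id, sm, gap_mode), epsilon)
}

# column-wise majority consensus of three sequences; ties (all three
# states distinct) resolved in favour of the first row
.triplet_median <- function(s1, s2, s3) {
  vapply(seq_along(s1), function(c) {
    st <- c(s1[c], s2[c], s3[c])
    tb <- table(st)
    if (max(tb) >= 2L) names(tb)[which.max(tb)] else s1[c]
  }, character(1))
}

#' Build a median-joining network
#'
#' Iterates: (i) compute the epsilon-relaxed minimum-spanning network
#' over the current node set; (ii) for every triplet of mutually
#' connected nodes, form the column-wise majority-consensus median
#' vector, breaking three-way ties in favour of the triplet member with
#' the smallest node index; (iii) admit each new median that strictly
#' lowers the cost of connecting the node set (minimum-spanning-tree
#' total weight). At fixpoint, median vectors of degree <= 1 are pruned
#' (observed haplotypes are always retained) and the epsilon-relaxed MSN
#' over the surviving nodes is returned. Median vectors get node ids
#' `mv1, mv2, ...` in order of creation.
#'
#' @inheritParams build_msn
#' @param epsilon the median-joining relaxation parameter; 0 reproduces
#'   the strict minimum-spanning backbone between insertions.
#' @param max_rounds iteration guard; exceeded only on a logic error
#'   since each round strictly lowers an integer-valued cost.
#' @return a `haplonet`; median-vector rows have `kind = "median"`,
#'   `hap_id = NA` and `count = 0`.
#' @export
build_mjn <- function(table, epsilon = 0L,
                      gap_mode = c("fifth_state", "ignore"),
                      max_rounds = NULL) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(inherits(table, "haplotype_table"), nrow(table) >= 1L)
  if (anyNA(table$sequence))
    stop("haplotype table has no sequences (label-only data); cannot build a network")
  if (is.null(max_rounds)) max_rounds <- max(10L, 10L * nrow(table))
  sm <- .seq_matrix(table$sequence)
  n_obs <- nrow(sm)
  seqs_key <- apply(sm, 1, paste, collapse = "")
  D <- .dist_matrix(sm, gap_mode)
  n_median <- 0L

  round <- 0L
  repeat {
    round <- round + 1L
    if (round > max_rounds)
      stop("median-joining did not converge within the iteration cap")
    idx <- .msn_edges(D, epsilon)
    n <- nrow(sm)
    adj <- matrix(FALSE, n, n)
    adj[idx] <- TRUE
    adj <- adj | t(adj)
    added <- FALSE
    if (n >= 3L) {
      for (u in seq_len(n - 2L)) for (v in (u + 1L):(n - 1L)) {
        if (!adj[u, v]) next
        for (w in (v + 1L):n) {
          if (!(adj[u, w] && adj[v, w])) next
          med <- .triplet_median(sm[u, ], sm[v, ], sm[w, ])
          key <- paste(med, collapse = "")
          if (key %in% seqs_key) next
          # accept iff the median lowers the connection cost
          dmed <- vapply(seq_len(n), function(i) {
            diff <- sm[i, ] != med
            if (gap_mode == "ignore") diff <- diff & sm[i, ] != "-" & med != "-"
            sum(diff)
          }, integer(1))
          D2 <- rbind(cbind(D, dmed), c(dmed, 0L))
          if (.mst_cost(D2) < .mst_cost(D)) {
            sm <- rbind(sm, med)
            seqs_key <- c(seqs_key, key)
            D <- D2
            n <- n + 1L
            adj <- rbind(cbind(adj, FALSE), FALSE)
            n_median <- n_median + 1L
            added <- TRUE
          }
        }
      }
    }
    if (!added) break
  }

  # prune median vectors that end up peripheral (degree <= 1)
  repeat {
    idx <- .msn_edges(D, epsilon)
    n <- nrow(sm)
    deg <- tabulate(c(idx[, 1], idx[, 2]), nbins = n)
    drop <- which(deg <= 1L & seq_len(n) > n_obs)
    if (length(drop) == 0L) break
    keep <- setdiff(seq_len(n), drop)
    sm <- sm[keep, , drop = FALSE]
    D <- D[keep, keep, drop = FALSE]
    seqs_key <- seqs_key[keep]
  }

  n <- nrow(sm)
  node_id <- c(table$hap_id, if (n > n_obs) paste0("mv", seq_len(n - n_obs)))
  kind <- c(rep("observed", n_obs), rep("median", n - n_obs))
  hap_id <- c(table$hap_id, rep(NA_character_, n - n_obs))
  count <- c(table$count, rep(0L, n - n_obs))
  sequences <- apply(sm, 1, paste, collapse = "")
  idx <- .msn_edges(D, epsilon)
  .finish_network(node_id, kind, hap_id, count, sequences,
                  .edges_df(idx, node_id, sm, gap_mode), epsilon)
}

#' @export
print.haplonet <- function(x, ...) {
  nm <- sum(x$nodes$kind == "median")
  cat(sprintf("Haplotype network: %d observed haplotype%s, %d median vector%s, %d edge%s (epsilon = %d)\n",
              nrow(x$nodes) - nm, if (nrow(x$nodes) - nm == 1L) "" else "s",
              nm, if (nm == 1L) "" else "s",
              nrow(x$edges), if (nrow(x$edges) == 1L) "" else "s",
              x$epsilon))
  invisible(x)
}

#' Total edge weight needed to connect a haplonet's nodes
#'
#' Minimum-spanning-tree weight over the node set's pairwise distances,
#' recomputed from the stored sequences.
#' @param net a `haplonet`.
#' @param gap_mode see [mutation_distance()].
#' @return integer.
#' @export
connection_cost <- function(net, gap_mode = c("fifth_state", "ignore")) {
  gap_mode <- match.arg(gap_mode)
  .mst_cost(.dist_matrix(.seq_matrix(net$nodes$sequence), gap_mode))
}

# igraph view of a haplonet (used for layout, export, connectivity checks)
.as_igraph <- function(net, links = NULL) {
  g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = FALSE)
  igraph::V(g)$name <- net$nodes$node_id
  igraph::V(g)$kind <- net$nodes$kind
  igraph::V(g)$count <- net$nodes$count
  if (nrow(net$edges) > 0L) {
    g <- igraph::add_edges(g, rbind(match(net$edges$from, net$nodes$node_id),
                                    match(net$edges$to, net$nodes$node_id)))
    igraph::E(g)$class <- "network"
    igraph::E(g)$length <- net$edges$length
    igraph::E(g)$positions <- vapply(net$edges$positions, paste,
                                     character(1), collapse = ",")
    igraph::E(g)$weight <- NA_integer_
  }
  if (!is.null(links) && nrow(links) > 0L) {
    e0 <- igraph::ecount(g)
    g <- igraph::add_edges(g, rbind(match(links$hap_u, net$nodes$node_id),
                                    match(links$hap_v, net$nodes$node_id)))
    idx <- (e0 + 1L):igraph::ecount(g)
    igraph::E(g)$class[idx] <- "cooccurrence"
    igraph::E(g)$weight[idx] <- links$weight
  }
  g
}
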