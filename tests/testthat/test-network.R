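test_that("mutation distance counts differing columns under both gap modes", {
  expect_equal(mutation_distance("ACGT", "ACGT"), list(count = 0L, positions = integer(0)))
  expect_equal(mutation_distance("ACGT", "ACGA"), list(count = 1L, positions = 4L))
  expect_equal(mutation_distance("AC-T", "ACTT")$count, 1L)
  expect_equal(mutation_distance("AC-T", "ACTT")$positions, 3L)
  expect_equal(mutation_distance("AC-T", "ACTT", gap_mode = "ignore")$count, 0L)
  # symmetric
  expect_equal(mutation_distance("AAGT", "ACGA"), mutation_distance("ACGA", "AAGT"))
  expect_error(mutation_distance("AC", "ACG"), "length mismatch")
})

test_that("minimum-spanning network equals the union of all MSTs", {
  # single haplotype: one node, no edges
  n1 <- build_msn(toy_table("ACGT"))
  expect_equal(nrow(n1$nodes), 1L)
  expect_equal(nrow(n1$edges), 0L)

  # distances 1,1,2: unique MST, the length-2 edge is excluded
  n2 <- build_msn(toy_table(c("AAAA", "AAAT", "AATT")))
  expect_equal(nrow(n2$edges), 2L)
  expect_equal(sort(n2$edges$length), c(1L, 1L))

  # mutually at distance 2: every edge is in some MST, all three kept
  seqs3 <- c("AA", "CC", "GG")
  expect_equal(unname(pair_dist(seqs3)[upper.tri(diag(3))]), c(2L, 2L, 2L))
  n3 <- build_msn(toy_table(seqs3))
  expect_equal(nrow(n3$edges), 3L)

  # random small cases against exhaustive spanning-tree enumeration
  set.seed(31)
  for (rep in 1:8) {
    seqs <- unique(replicate(5, paste(sample(c("A", "C", "G"), 5, replace = TRUE),
                                      collapse = "")))
    net <- build_msn(toy_table(seqs))
    D <- pair_dist(seqs)
    want <- oracle_all_mst_edges(D)
    got <- cbind(match(net$edges$from, paste0("h", seq_along(seqs))),
                 match(net$edges$to, paste0("h", seq_along(seqs))))
    key <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
    expect_equal(key(got), key(want))
  }
})

test_that("edge lengths equal the number of listed mutated positions", {
  set.seed(32)
  seqs <- unique(replicate(6, paste(sample(c("A", "C", "G", "T"), 6,
                                           replace = TRUE), collapse = "")))
  for (net in list(build_msn(toy_table(seqs)), build_mjn(toy_table(seqs)))) {
    expect_equal(net$edges$length, lengths(net$edges$positions))
    seq_of <- stats::setNames(net$nodes$sequence, net$nodes$node_id)
    for (i in seq_len(nrow(net$edges))) {
      md <- mutation_distance(seq_of[[net$edges$from[i]]],
                              seq_of[[net$edges$to[i]]])
      expect_equal(net$edges$positions[[i]], md$positions)
    }
  }
})

test_that("median-joining inserts the cost-reducing consensus vector", {
  # three sequences pairwise 2 apart whose majority median links all at 1:
  # connection cost drops from 4 (MST) to 3 (star through the median)
  tab <- toy_table(c("AAA", "ATT", "TAT"))
  expect_equal(haploweb:::.mst_cost(pair_dist(c("AAA", "ATT", "TAT"))), 4L)
  net <- build_mjn(tab, epsilon = 0)
  med <- net$nodes[net$nodes$kind == "median", ]
  expect_equal(nrow(med), 1L)
  expect_equal(med$sequence, "AAT")
  expect_true(all(net$edges$length == 1L))
  expect_equal(connection_cost(net), 3L)

  # single haplotype trivially yields one node
  expect_equal(nrow(build_mjn(toy_table("ACGT"))$nodes), 1L)
})

test_that("median vectors in the emitted network have degree at least 2", {
  set.seed(33)
  for (rep in 1:10) {
    seqs <- unique(replicate(sample(3:6, 1),
                             paste(sample(c("A", "T"), 6, replace = TRUE),
                                   collapse = "")))
    net <- build_mjn(toy_table(seqs))
    deg <- table(factor(c(net$edges$from, net$edges$to),
                        levels = net$nodes$node_id))
    expect_true(all(deg[net$nodes$node_id[net$nodes$kind == "median"]] >= 2L))
  }
})

test_that("networks are connected and retain every observed haplotype", {
  set.seed(34)
  for (rep in 1:10) {
    k <- sample(2:7, 1)
    seqs <- unique(replicate(k, paste(sample(c("A", "C", "G", "T"), 8,
                                             replace = TRUE), collapse = "")))
    tab <- toy_table(seqs)
    for (net in list(build_msn(tab), build_mjn(tab),
                     build_mjn(tab, epsilon = 1))) {
      expect_true(all(paste0("h", seq_along(seqs)) %in% net$nodes$node_id))
      g <- haploweb:::.as_igraph(net)
      expect_true(igraph::is_connected(g))
    }
  }
})

test_that("median-joining connection cost never exceeds the observed-only MST", {
  set.seed(35)
  for (rep in 1:10) {
    seqs <- unique(replicate(5, paste(sample(c("A", "C", "T"), 7,
                                             replace = TRUE), collapse = "")))
    net <- build_mjn(toy_table(seqs))
    expect_lte(connection_cost(net),
               oracle_mst_cost(pair_dist(seqs)))
  }
})

test_that("median-joining node set matches the brute-force closure on small inputs", {
  set.seed(36)
  for (rep in 1:12) {
    k <- sample(3:6, 1)
    len <- sample(4:8, 1)
    seqs <- unique(replicate(k, paste(sample(c("A", "G"), len, replace = TRUE),
                                      collapse = "")))
    if (length(seqs) < 2L) next
    net <- build_mjn(toy_table(seqs))
    expect_equal(sort(net$nodes$sequence), oracle_mjn_nodes(seqs),
                 info = paste(seqs, collapse = " "))
  }
})

test_that("the iteration guard trips instead of looping forever", {
  tab <- toy_table(c("AAA", "ATT", "TAT"))
  expect_error(build_mjn(tab, max_rounds = 0L), "converge")
})
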