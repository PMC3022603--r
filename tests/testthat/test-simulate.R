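test_that("the generator is deterministic and respects its guarantees", {
  cfg <- sim_config(seed = 101)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$datasets, b$datasets)
  expect_identical(a$truth, b$truth)
  # and writes byte-identical files
  d1 <- tempfile(); d2 <- tempfile()
  write_sim(a, d1); write_sim(b, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  # species pools are disjoint at every marker
  for (m in names(a$pools)) {
    p <- a$pools[[m]]
    expect_length(intersect(p[[1]], p[[2]]), 0L)
  }

  # truth partition matches the configured sizes
  expect_equal(block_sizes(a$truth), c(20L, 20L))
})

test_that("degenerate configs behave as defined", {
  # one species, no intra variation: one haplotype, all homozygous, 1 sl-FFR
  cfg <- sim_config(n_species = 1, individuals_per_species = 6,
                    intra_mutations = 0, intra_haplotypes = 1,
                    markers = c(nuc = 2L), seed = 9)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$datasets$nuc$table), 1L)
  expect_equal(delineate_sl_ffrs(sim$datasets$nuc$dataset)$k, 1L)

  # config validation
  expect_error(sim_config(inter_mutations = 3, intra_mutations = 2),
               "2\\*intra_mutations")
  expect_error(sim_config(seq_length = 10), "too short")
})

test_that("each marker partition refines the truth and scoring recovers the split", {
  sim <- simulate_dataset(sim_config(seed = 1))
  parts <- lapply(sim$datasets, function(d) marker_partition(d$dataset))
  for (p in parts) {
    for (b in p$blocks) {
      hosts <- vapply(sim$truth$blocks, function(tb) all(b %in% tb),
                      logical(1))
      expect_equal(sum(hosts), 1L)
    }
  }
  st <- score_bipartitions(unname(parts))
  top <- st[st$percent == 100L, ]
  sizes <- vapply(top$side, length, integer(1))
  expect_true(any(pmin(sizes, 40L - sizes) == 20L))
})

test_that("severe undersampling fragments the sl-FFRs", {
  # 2 individuals/species: singleton FFRs appear under some seeds
  frag <- vapply(1:12, function(s) {
    sim <- simulate_dataset(sim_config(individuals_per_species = 2, seed = s))
    p <- delineate_sl_ffrs(sim$datasets$nuc1$dataset)
    p$k
  }, integer(1))
  expect_gt(max(frag), 2L)
})

test_that("recovery: 20 seeded runs reconcile to the true species partition", {
  fails <- integer(0)
  for (s in 1:20) {
    sim <- simulate_dataset(sim_config(seed = s))
    d <- delimit(sim$datasets)
    ok <- identical(partition_signature(d$reconciliation$partition),
                    partition_signature(sim$truth))
    if (!ok) fails <- c(fails, s)
  }
  expect_identical(fails, integer(0),
                   info = paste("failed seeds:", paste(fails, collapse = ", ")))
})

test_that("one F1 hybrid collapses the ml-FFR join to a single block", {
  clean <- simulate_dataset(sim_config(seed = 7))
  join0 <- ml_ffr_join(lapply(clean$datasets[c("nuc1", "nuc2")],
                              function(d) delineate_sl_ffrs(d$dataset)))
  expect_equal(join0$k, 2L)

  sim <- simulate_dataset(sim_config(seed = 7, f1_hybrid_count = 1))
  expect_equal(nrow(sim$anomalies), 1L)
  join1 <- ml_ffr_join(lapply(sim$datasets[c("nuc1", "nuc2")],
                              function(d) delineate_sl_ffrs(d$dataset)))
  expect_equal(join1$k, 1L)

  # and shows in the haploweb as a weight-1 link between common haplotypes
  links <- cooccurrence_links(sim$datasets$nuc1$dataset)
  tab <- sim$datasets$nuc1$table
  hyb <- grep("^hyb_", sim$truth$universe, value = TRUE)
  g <- sim$datasets$nuc1$dataset$genotypes[[hyb]]
  cross <- links[links$hap_u == min(g) & links$hap_v == max(g), ]
  expect_equal(cross$weight, 1L)
})

test_that("one introgressed allele at 1 of 3 markers leaves the split at 67%", {
  sim <- simulate_dataset(sim_config(seed = 7, introgressed_allele_count = 1))
  expect_equal(sim$anomalies$kind, "introgression")
  d <- delimit(sim$datasets)
  truth_sizes <- block_sizes(sim$truth)
  # the species bipartition survives the cutoff at 2/3 support
  kept <- d$reconciliation$kept
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$percent, 67L)
  expect_equal(kept$support, 2 / 3)
  expect_equal(partition_signature(d$reconciliation$partition),
               partition_signature(sim$truth))
  # but the contaminated marker no longer supports it on its own
  expect_length(kept$supported_by[[1]], 2L)
  expect_false("nuc1" %in% kept$supported_by[[1]])
})

test_that("a shared ancestral haplotype merges the affected marker's FFRs", {
  sim <- simulate_dataset(sim_config(seed = 11, shared_ancestral_count = 1))
  expect_equal(sim$anomalies$kind, "shared_ancestral")
  p_bad <- delineate_sl_ffrs(sim$datasets$nuc1$dataset)
  expect_equal(p_bad$k, 1L)
  # the other markers still support the true split: 2/3 survives
  d <- delimit(sim$datasets)
  expect_equal(partition_signature(d$reconciliation$partition),
               partition_signature(sim$truth))
})

test_that("anomaly counts beyond the population are rejected", {
  expect_error(simulate_dataset(sim_config(individuals_per_species = 3,
                                           introgressed_allele_count = 5,
                                           seed = 2)))
  expect_error(inject_anomalies(simulate_dataset(sim_config(n_species = 1,
                                                            seed = 2)),
                                f1_hybrid_count = 1), "2 species")
})
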