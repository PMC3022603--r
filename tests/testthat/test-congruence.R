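test_that("a k-block partition supports 2^(k-1)-1 bipartitions", {
  for (k in c(2L, 3L, 4L)) {
    p <- random_partition(10, k)
    expect_length(partition_bipartitions(p), 2L^(k - 1L) - 1L)
  }
  expect_length(partition_bipartitions(new_partition(list(c("a", "b")))), 0L)

  # verified against exhaustive enumeration over individuals up to k = 12
  set.seed(51)
  for (k in c(2L, 3L, 5L, 8L, 12L)) {
    inds <- sprintf("I%02d", seq_len(k))
    p <- new_partition(as.list(inds), label = "singletons")
    sides <- partition_bipartitions(p)
    expect_length(sides, 2L^(k - 1L) - 1L)
    # brute force: every subset of individuals not containing the smallest
    count <- 0L
    for (m in seq_len(2L^(k - 1L) - 1L)) {
      side <- inds[-1][bitwAnd(m, bitwShiftL(1L, 0:(k - 2L))) != 0L]
      if (supports(p, side)) count <- count + 1L
    }
    expect_equal(count, 2L^(k - 1L) - 1L)
    # canonical sides never contain the smallest individual
    expect_false(any(vapply(sides, function(s) inds[1] %in% s, logical(1))))
  }

  expect_error(partition_bipartitions(random_partition(30, 25)), "cap")
})

test_that("support of a bipartition means every block lies on one side", {
  p <- new_partition(list(c("a", "b"), "c"))
  expect_true(supports(p, c("a", "b")))
  expect_true(supports(p, "c"))        # same split, other side
  expect_false(supports(p, c("a", "c")))
  expect_error(supports(p, c("a", "z")), "universe")

  # membership in the enumeration agrees with the predicate, brute force
  set.seed(52)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    p <- random_partition(n, sample(2:4, 1))
    inds <- p$universe
    enum <- vapply(partition_bipartitions(p), paste, character(1),
                   collapse = "|")
    for (m in seq_len(2L^(n - 1L) - 1L)) {
      side <- inds[-1][bitwAnd(m, bitwShiftL(1L, 0:(n - 2L))) != 0L]
      expect_equal(supports(p, side),
                   paste(sort(side), collapse = "|") %in% enum)
    }
  }
})

test_that("bipartition scoring pools markers and rounds half-up", {
  a <- new_partition(list(c("a", "b"), c("c", "d")), label = "m1")
  expect_equal(score_bipartitions(list(a))$percent, 100L)

  b_same <- new_partition(list(c("a", "b"), c("c", "d")), label = "m2")
  st <- score_bipartitions(list(a, b_same))
  expect_equal(nrow(st), 1L)
  expect_equal(st$percent, 100L)

  b_diff <- new_partition(list(c("a", "c"), c("b", "d")), label = "m2")
  st2 <- score_bipartitions(list(a, b_diff))
  expect_equal(nrow(st2), 2L)
  expect_equal(st2$percent, c(50L, 50L))

  # 1/3 prints as 33 (half-up), 2/3 as 67
  c3 <- new_partition(list(c("a", "d"), c("b", "c")), label = "m3")
  st3 <- score_bipartitions(list(a, b_diff, c3))
  expect_true(all(st3$percent == 33L))
  st23 <- score_bipartitions(list(a, b_same, c3))
  expect_equal(sort(unique(st23$percent)), c(33L, 67L))

  # universe mismatch errors unless restricted to the common set
  d <- new_partition(list(c("a", "b"), "c"), label = "m4")
  expect_error(score_bipartitions(list(a, d)), "same set of individuals")
  str <- score_bipartitions(list(a, d), restrict_to_common = TRUE)
  expect_setequal(attr(str, "universe"), c("a", "b", "c"))
})

test_that("scoring is invariant under renaming of individuals", {
  parts <- clipperton_partitions()
  st <- score_bipartitions(unname(parts))
  # apply a random bijection to the sample names
  set.seed(53)
  old <- parts$ITS2$universe
  new <- sprintf("X%03d", sample(length(old)))
  rename <- stats::setNames(new, old)
  renamed <- lapply(parts, function(p)
    new_partition(lapply(p$blocks, function(b) unname(rename[b])),
                  label = p$label))
  st2 <- score_bipartitions(unname(renamed))
  expect_equal(nrow(st2), nrow(st))
  expect_equal(sort(st2$percent), sort(st$percent))
  # the unordered split sizes are invariant (canonical orientation is not)
  n <- length(old)
  expect_equal(sort(pmin(st2$n_side, n - st2$n_side)),
               sort(pmin(st$n_side, n - st$n_side)))
})

test_that("the three-marker worked example yields 13 bipartitions, one unanimous", {
  parts <- clipperton_partitions()
  expect_equal(vapply(parts, function(p) p$k, integer(1), USE.NAMES = FALSE),
               c(4L, 2L, 4L))
  expect_equal(block_sizes(parts$ITS2), c(55L, 17L, 1L, 1L))
  expect_equal(block_sizes(parts$ATPSb), c(57L, 17L))
  expect_equal(block_sizes(parts$mito), c(52L, 17L, 3L, 2L))

  st <- score_bipartitions(unname(parts))
  expect_equal(nrow(st), 13L)
  expect_equal(sum(st$n_support == 3L), 1L)
  expect_equal(sum(st$n_support == 2L), 0L)
  expect_equal(st$percent, c(100L, rep(33L, 12L)))
  # the unanimous split separates 17 individuals (species B) from 57;
  # the canonical side is the one without the smallest sample name
  expect_equal(sort(c(st$n_side[1], 74L - st$n_side[1])), c(17L, 57L))

  r <- reconcile(st, threshold = 0.5)
  expect_equal(nrow(r$kept), 1L)
  expect_equal(block_sizes(r$partition), c(57L, 17L))
  expect_equal(nrow(r$conflicts), 0L)
})

test_that("partition join merges chained blocks; meet intersects them", {
  one <- new_partition(list(c("a", "b"), "c"), label = "p")
  expect_equal(partition_signature(ml_ffr_join(list(one))),
               partition_signature(one))
  # transitivity forces a single block
  x <- new_partition(list("a", c("b", "c")))
  y <- new_partition(list(c("a", "b"), "c"))
  expect_equal(ml_ffr_join(list(x, y))$k, 1L)
  expect_equal(partition_signature(partition_meet(list(x, y))),
               c("a", "b", "c"))
  expect_equal(partition_signature(partition_meet(list(x, x))),
               partition_signature(x))

  parts <- clipperton_partitions()
  j <- ml_ffr_join(list(parts$ITS2, parts$ATPSb))
  expect_equal(block_sizes(j), c(57L, 17L))

  m <- partition_meet(unname(parts))
  expect_equal(block_sizes(m), c(51L, 17L, 3L, 1L, 1L, 1L))
  singletons <- unlist(m$blocks[lengths(m$blocks) == 1L])
  expect_true("05Clip048" %in% singletons)
})

test_that("join and meet behave as lattice operations", {
  set.seed(54)
  refines <- function(fine, coarse) {
    all(vapply(fine$blocks, function(b)
      any(vapply(coarse$blocks, function(cb) all(b %in% cb), logical(1))),
      logical(1)))
  }
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    ps <- lapply(1:3, function(i) random_partition(n, sample(2:4, 1),
                                                   label = paste0("p", i)))
    j12 <- ml_ffr_join(ps[1:2]); m12 <- partition_meet(ps[1:2])
    # commutative
    expect_equal(partition_signature(j12),
                 partition_signature(ml_ffr_join(ps[2:1])))
    expect_equal(partition_signature(m12),
                 partition_signature(partition_meet(ps[2:1])))
    # associative
    expect_equal(partition_signature(ml_ffr_join(ps)),
                 partition_signature(ml_ffr_join(list(j12, ps[[3]]))))
    expect_equal(partition_signature(partition_meet(ps)),
                 partition_signature(partition_meet(list(m12, ps[[3]]))))
    # idempotent
    expect_equal(partition_signature(ml_ffr_join(list(ps[[1]], ps[[1]]))),
                 partition_signature(ps[[1]]))
    # join coarser than every input, meet finer
    for (p in ps[1:2]) {
      expect_true(refines(p, j12))
      expect_true(refines(m12, p))
    }
  }
})

test_that("a unanimous bipartition is a 2-block coarsening of meet and inputs", {
  parts <- clipperton_partitions()
  st <- score_bipartitions(unname(parts))
  top <- st$side[[which(st$n_support == 3L)]]
  m <- partition_meet(unname(parts))
  two <- new_partition(list(top, setdiff(m$universe, top)))
  for (b in m$blocks)
    expect_true(all(b %in% top) || !any(b %in% top))
  for (p in parts) expect_true(supports(p, top))
})

test_that("reconciliation thresholds strictly and reports conflicts", {
  parts <- clipperton_partitions()
  st <- score_bipartitions(unname(parts))
  # a single-block marker supports nothing: empty table, one inclusive group
  single <- score_bipartitions(list(new_partition(list(c("a", "b")),
                                                  label = "k1")))
  expect_equal(nrow(single), 0L)
  empty <- reconcile(single)
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(empty$partition$k, 1L)
  expect_setequal(empty$partition$blocks[[1]], c("a", "b"))

  # threshold 0 keeps all 13 rows; the overlapping 33% rows conflict
  r0 <- suppressWarnings(reconcile(st, threshold = 0))
  expect_equal(nrow(r0$kept), 13L)
  expect_gt(nrow(r0$conflicts), 0L)
  expect_warning(reconcile(st, threshold = 0), "incompatible")
  # brute-force pairwise compatibility count agrees
  u <- attr(st, "universe")
  n_bad <- 0L
  for (i in 1:12) for (j in (i + 1L):13L) {
    a <- st$side[[i]]; b <- st$side[[j]]
    ca <- setdiff(u, a); cb <- setdiff(u, b)
    if (length(intersect(a, b)) > 0L && length(intersect(a, cb)) > 0L &&
        length(intersect(ca, b)) > 0L && length(intersect(ca, cb)) > 0L)
      n_bad <- n_bad + 1L
  }
  expect_equal(nrow(r0$conflicts), n_bad)
})
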