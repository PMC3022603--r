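#' Bipartition enumeration, support scoring and reconciliation
#'
#' A *bipartition* splits the full sample set into two complementary
#' non-empty groups. A marker's partition (sl-FFRs or haplogroups)
#' *supports* a bipartition when each of its blocks lies entirely on one
#' side, i.e. the bipartition is a union of blocks versus the rest. A
#' partition with k blocks therefore supports 2^(k-1) - 1 distinct
#' non-trivial bipartitions. Scoring every bipartition by the fraction of
#' independent datasets supporting it quantifies multi-marker congruence;
#' the well-supported bipartitions are then reconciled into a final
#' grouping of putative species.
#'
#' Bipartitions are canonicalized as the side NOT containing the
#' lexicographically smallest individual of the universe, so each
#' unordered split has a unique representation.
#'
#' @name congruence
NULL

# canonical key for a side (a character vector of ids); universe needed to
# orient the split
.canonical_side <- function(side, universe) {
  side <- sort(unique(as.character(side)))
  if (length(side) == 0L || length(side) >= length(universe))
    stop("a bipartition side must be a non-empty proper subset of the universe")
  if (!all(side %in% universe)) stop("side contains ids outside the universe")
  if (universe[1] %in% side) side <- sort(setdiff(universe, side))
  side
}

.side_key <- function(side) paste(side, collapse = "\x1f")

#' Enumerate the bipartitions supported by a partition
#'
#' Returns one canonical bipartition per non-trivial unordered split of
#' the partition's blocks into two groups: 2^(k-1) - 1 of them for k
#' blocks, none for k = 1.
#'
#' @param p a [new_partition()] object.
#' @param cap refuse to enumerate when `p$k` exceeds this (the count grows
#'   as 2^(k-1)); raise deliberately if you really want more.
#' @return list of canonical sides (sorted character vectors); empty list
#'   for a single-block partition.
#' @examples
#' p <- new_partition(list(c("a", "b"), "c", "d"))
#' length(partition_bipartitions(p))  # 2^(3-1) - 1 = 3
#' @export
partition_bipartitions <- function(p, cap = 20L) {
  stopifnot(inherits(p, "partition"))
  if (p$k > cap)
    stop(sprintf(paste0("partition has %d blocks; enumerating 2^(%d)-1 ",
                        "bipartitions is refused at cap = %d. Raise 'cap' ",
                        "explicitly if this is intended."), p$k, p$k - 1L, cap))
  if (p$k == 1L) return(list())
  # fix the block holding the smallest individual on the implicit side;
  # every non-empty subset of the remaining blocks is a canonical side
  anchor <- which(vapply(p$blocks, function(b) p$universe[1] %in% b, logical(1)))
  rest <- setdiff(seq_len(p$k), anchor)
  out <- vector("list", 2L^length(rest) - 1L)
  idx <- 0L
  for (m in seq_len(2L^length(rest) - 1L)) {
    pick <- rest[bitwAnd(m, bitwShiftL(1L, seq_along(rest) - 1L)) != 0L]
    idx <- idx + 1L
    out[[idx]] <- sort(unlist(p$blocks[pick], use.names = FALSE))
  }
  out
}

#' Does a partition support a bipartition?
#'
#' TRUE iff every block of `p` lies entirely within one side of the
#' bipartition, i.e. the side is a union of blocks of `p`.
#'
#' @param p a `partition`.
#' @param side one side of the bipartition, as a character vector of
#'   individual ids (either side may be given).
#' @return logical scalar.
#' @export
supports <- function(p, side) {
  stopifnot(inherits(p, "partition"))
  side <- .canonical_side(side, p$universe)
  in_side <- p$universe %in% side
  names(in_side) <- p$universe
  for (b in p$blocks) {
    v <- in_side[b]
    if (any(v) && !all(v)) return(FALSE)
  }
  TRUE
}

#' Score all bipartitions supported by at least one marker
#'
#' Enumerates each input partition's supported bipartitions, pools them,
#' and scores every distinct bipartition by the fraction of input
#' datasets supporting it (each partition counts as one independent
#' dataset). Support percentages are rounded half-up for display; exact
#' fractions are kept for thresholding.
#'
#' @param partitions list of `partition` objects over the same universe.
#' @param restrict_to_common if TRUE, first restrict every partition to
#'   the individuals present in all universes instead of erroring on a
#'   mismatch.
#' @param cap per-partition enumeration cap, see [partition_bipartitions()].
#' @return a `support_table`: data.frame with list-column `side`, columns
#'   `n_side`, `n_support`, `support` (fraction), `percent` (integer,
#'   half-up), list-column `supported_by` (partition labels), attribute
#'   `M` (number of datasets) and `universe`. Rows are sorted by
#'   descending support, then by canonical side.
#' @export
score_bipartitions <- function(partitions, restrict_to_common = FALSE,
                               cap = 20L) {
  if (inherits(partitions, "partition")) partitions <- list(partitions)
  stopifnot(length(partitions) >= 1L,
            all(vapply(partitions, inherits, logical(1), "partition")))
  if (restrict_to_common) {
    common <- Reduce(intersect, lapply(partitions, `[[`, "universe"))
    partitions <- lapply(partitions, restrict_partition, ids = common)
  }
  universe <- .check_same_universe(partitions, "bipartition scoring")
  M <- length(partitions)
  labels <- vapply(partitions, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    labels <- make.unique(labels, sep = "#")

  sides <- list()
  supp <- list()
  for (i in seq_len(M)) {
    for (side in partition_bipartitions(partitions[[i]], cap = cap)) {
      key <- .side_key(side)
      if (is.null(supp[[key]])) {
        sides[[key]] <- side
        supp[[key]] <- labels[i]
      } else {
        supp[[key]] <- c(supp[[key]], labels[i])
      }
    }
  }
  keys <- names(sides)
  if (is.null(keys)) keys <- character(0)
  n_support <- vapply(supp[keys], length, integer(1))
  frac <- n_support / M
  ord <- order(-frac, keys)
  keys <- keys[ord]
  tab <- data.frame(n_side = vapply(sides[keys], length, integer(1)),
                    n_support = n_support[ord],
                    support = frac[ord],
                    percent = as.integer(floor(frac[ord] * 100 + 0.5)),
                    stringsAsFactors = FALSE)
  tab$side <- unname(sides[keys])
  tab$supported_by <- unname(supp[keys])
  rownames(tab) <- NULL
  structure(tab[, c("side", "n_side", "supported_by", "n_support",
                    "support", "percent")],
            M = M, universe = universe, labels = labels,
            class = c("support_table", "data.frame"))
}

#' @export
print.support_table <- function(x, max_ids = 5L, ...) {
  M <- attr(x, "M")
  cat(sprintf("Bipartition support over %d independent dataset%s (%d row%s)\n",
              M, if (M == 1L) "" else "s",
              nrow(x), if (nrow(x) == 1L) "" else "s"))
  labels <- attr(x, "labels")
  for (i in seq_len(nrow(x))) {
    side <- x$side[[i]]
    shown <- if (length(side) > max_ids)
      paste0(paste(side[seq_len(max_ids)], collapse = "+"), "+... (", length(side), ")")
    else paste(side, collapse = "+")
    marks <- vapply(labels, function(l) if (l %in% x$supported_by[[i]]) "x" else ".",
                    character(1))
    cat(sprintf("%3d  %-45s %s %4d%%\n", i, paste(shown, "vs all others"),
                paste(marks, collapse = " "), x$percent[i]))
  }
  invisible(x)
}

#' Multilocus FFRs: finest common coarsening (partition join)
#'
#' Two individuals end up in the same multilocus FFR when they are
#' connected through a chain of shared single-locus blocks: the
#' transitive closure of "same block in at least one input", i.e. the
#' join of the input partitions in the partition lattice. Computed by
#' union-find.
#'
#' @param partitions list of `partition` objects over the same universe.
#' @param label label of the result.
#' @return a `partition`.
#' @export
ml_ffr_join <- function(partitions, label = "ml-FFR") {
  if (inherits(partitions, "partition")) partitions <- list(partitions)
  stopifnot(length(partitions) >= 1L)
  universe <- .check_same_universe(partitions, "the ml-FFR join")
  parent <- seq_along(universe)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (p in partitions) {
    for (b in p$blocks) {
      ix <- match(b, universe)
      r <- find(ix[1])
      for (j in ix[-1]) parent[find(j)] <- r
    }
  }
  roots <- vapply(seq_along(universe), find, integer(1))
  partition_from_membership(universe, roots, label = label)
}

#' Coarsest common refinement (partition meet)
#'
#' Blocks of the meet are the non-empty intersections of one block from
#' each input partition: the groups of individuals that no input ever
#' separates. These intersection regions need not be sl-FFRs of any
#' single marker.
#'
#' @inheritParams ml_ffr_join
#' @return a `partition`.
#' @export
partition_meet <- function(partitions, label = "meet") {
  if (inherits(partitions, "partition")) partitions <- list(partitions)
  stopifnot(length(partitions) >= 1L)
  universe <- .check_same_universe(partitions, "the partition meet")
  keys <- do.call(paste, c(lapply(partitions, function(p)
    .partition_membership(p)), list(sep = "/")))
  partition_from_membership(universe, keys, label = label)
}

#' Reconcile a support table at a threshold
#'
#' Keeps bipartitions whose support fraction strictly exceeds
#' `threshold` (so 1/3 is dropped at 0.5 and 2/3 survives), verifies the
#' kept bipartitions are pairwise compatible (one side nests inside a
#' side of the other, or the sides are disjoint), and returns the final
#' grouping: the meet of the kept bipartitions viewed as 2-block
#' partitions. Incompatible kept bipartitions are reported as conflicts,
#' never silently resolved; the returned partition is still the meet,
#' which over-splits rather than invents a resolution.
#'
#' @param table a [score_bipartitions()] result.
#' @param threshold support fraction cutoff in `[0, 1)`; default 0.5.
#' @return a `reconciliation`: list with `kept` (data.frame subset of the
#'   table), `partition` (final grouping, label "reconciled"),
#'   `conflicts` (data.frame of incompatible kept pairs, 0 rows when
#'   clean) and `threshold`.
#' @export
reconcile <- function(table, threshold = 0.5) {
  stopifnot(inherits(table, "support_table"),
            is.numeric(threshold), threshold >= 0, threshold < 1)
  universe <- attr(table, "universe")
  keep <- table$support > threshold
  kept <- table[keep, , drop = FALSE]
  conflicts <- data.frame(row_i = integer(), row_j = integer())
  n <- nrow(kept)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      a <- kept$side[[i]]; b <- kept$side[[j]]
      ca <- setdiff(universe, a); cb <- setdiff(universe, b)
      # splits are compatible iff one of the four corner intersections is empty
      compatible <- length(intersect(a, b)) == 0L ||
        length(intersect(a, cb)) == 0L ||
        length(intersect(ca, b)) == 0L ||
        length(intersect(ca, cb)) == 0L
      if (!compatible)
        conflicts <- rbind(conflicts, data.frame(row_i = i, row_j = j))
    }
  }
  if (nrow(conflicts) > 0L)
    warning(sprintf("%d pair%s of kept bipartitions are incompatible; see $conflicts",
                    nrow(conflicts), if (nrow(conflicts) == 1L) "" else "s"))
  parts <- lapply(kept$side, function(s)
    new_partition(list(s, setdiff(universe, s)), universe = universe))
  final <- if (length(parts) == 0L)
    new_partition(list(universe), label = "reconciled")
  else {
    p <- partition_meet(parts, label = "reconciled")
    p
  }
  structure(list(kept = kept, partition = final, conflicts = conflicts,
                 threshold = threshold),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("Reconciliation at support > %g: %d bipartition%s kept\n",
              x$threshold, nrow(x$kept), if (nrow(x$kept) == 1L) "" else "s"))
  if (nrow(x$conflicts) > 0L)
    cat(sprintf("  CONFLICT: %d incompatible kept pair%s\n", nrow(x$conflicts),
                if (nrow(x$conflicts) == 1L) "" else "s"))
  cat(sprintf("Final grouping: %d group%s of sizes %s\n", x$partition$k,
              if (x$partition$k == 1L) "" else "s",
              paste(block_sizes(x$partition), collapse = ", ")))
  invisible(x)
}

#' Write a support table
#'
#' `write_support_tsv()` writes a flat TSV; `write_support_md()` writes a
#' Markdown table with one check-mark column per dataset;
#' `write_support_json()` writes the full table with exact fractions.
#'
#' @param table a `support_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_support_tsv <- function(table, path) {
  out <- data.frame(row = seq_len(nrow(table)),
                    side = vapply(table$side, paste, character(1), collapse = ","),
                    n_side = table$n_side,
                    supported_by = vapply(table$supported_by, paste,
                                          character(1), collapse = ","),
                    n_support = table$n_support,
                    support = table$support,
                    percent = table$percent)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_support_tsv
#' @export
write_support_md <- function(table, path) {
  labels <- attr(table, "labels")
  hdr <- paste0("| # | Bipartition | ", paste(labels, collapse = " | "),
                " | support |")
  sep <- paste0("|---|---|", paste(rep("---|", length(labels)), collapse = ""),
                "---|")
  lines <- c(hdr, sep)
  for (i in seq_len(nrow(table))) {
    side <- table$side[[i]]
    desc <- if (length(side) > 5L)
      sprintf("%s+... (%d samples) vs. all others",
              paste(side[1:5], collapse = "+"), length(side))
    else sprintf("%s vs. all others", paste(side, collapse = "+"))
    marks <- vapply(labels, function(l)
      if (l %in% table$supported_by[[i]]) "√" else "", character(1))
    lines <- c(lines, paste0("| ", i, " | ", desc, " | ",
                             paste(marks, collapse = " | "), " | ",
                             table$percent[i], "% |"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_support_tsv
#' @export
write_support_json <- function(table, path) {
  rows <- lapply(seq_len(nrow(table)), function(i) list(
    row = i,
    side = table$side[[i]],
    supported_by = table$supported_by[[i]],
    n_support = table$n_support[i],
    support_numerator = table$n_support[i],
    support_denominator = attr(table, "M"),
    percent = table$percent[i]))
  jsonlite::write_json(list(M = attr(table, "M"), bipartitions = rows),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
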