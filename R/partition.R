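#' Partitions of a sample set
#'
#' A `partition` divides a fixed set of individuals (the *universe*) into
#' disjoint, non-empty blocks that cover it. Partitions are the common
#' currency of the package: sl-FFRs from diploid markers, haplogroups from
#' haploid markers, multilocus FFRs, and the species truth of simulated
#' data are all partitions over the same universe.
#'
#' Blocks are stored sorted internally and ordered by decreasing size,
#' ties broken by the lexicographically smallest member, so printed and
#' written output is stable across runs.
#'
#' @param blocks list of character vectors, the blocks (disjoint, non-empty).
#' @param universe optional character vector of all individual ids; defaults
#'   to the union of the blocks. Must equal that union when given.
#' @param label short name for the partition (typically the marker name).
#' @return an object of class `partition` with fields `label`, `universe`
#'   (sorted), `blocks` and `k` (number of blocks).
#' @examples
#' p <- new_partition(list(c("a", "b"), "c"), label = "toy")
#' p$k
#' @export
new_partition <- function(blocks, universe = NULL, label = "") {
  if (!is.list(blocks) || length(blocks) == 0L)
    stop("'blocks' must be a non-empty list of character vectors")
  blocks <- lapply(blocks, function(b) sort(unique(as.character(b))))
  if (any(lengths(blocks) == 0L)) stop("blocks must be non-empty")
  all_ids <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("blocks are not disjoint: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  if (is.null(universe)) {
    universe <- sort(all_ids)
  } else {
    universe <- sort(unique(as.character(universe)))
    if (!setequal(universe, all_ids))
      stop("blocks do not cover the universe exactly; missing: ",
           paste(setdiff(universe, all_ids), collapse = ", "),
           "; extraneous: ", paste(setdiff(all_ids, universe), collapse = ", "))
  }
  ord <- order(-lengths(blocks), vapply(blocks, `[`, character(1), 1L))
  blocks <- unname(blocks[ord])
  structure(list(label = as.character(label), universe = universe,
                 blocks = blocks, k = length(blocks)),
            class = "partition")
}

#' Build a partition from a membership vector
#'
#' @param ids character vector of individual ids.
#' @param groups vector (same length) of group assignments.
#' @param label partition label.
#' @return a [new_partition()] object.
#' @export
partition_from_membership <- function(ids, groups, label = "") {
  stopifnot(length(ids) == length(groups))
  new_partition(split(as.character(ids), as.character(groups)), label = label)
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition '%s': %d individuals in %d block%s\n",
              x$label, length(x$universe), x$k, if (x$k == 1L) "" else "s"))
  sizes <- lengths(x$blocks)
  for (i in seq_len(min(x$k, 10L))) {
    b <- x$blocks[[i]]
    shown <- if (length(b) > 6L) c(b[1:6], "...") else b
    cat(sprintf("  [%d] n=%d: %s\n", i, sizes[i], paste(shown, collapse = ", ")))
  }
  if (x$k > 10L) cat(sprintf("  ... and %d more blocks\n", x$k - 10L))
  invisible(x)
}

#' Block sizes of a partition
#' @param p a `partition`.
#' @return integer vector of block sizes, in stored (decreasing) order.
#' @export
block_sizes <- function(p) {
  stopifnot(inherits(p, "partition"))
  lengths(p$blocks)
}

# membership lookup: named integer vector individual -> block index
.partition_membership <- function(p) {
  m <- rep.int(seq_len(p$k), lengths(p$blocks))
  names(m) <- unlist(p$blocks, use.names = FALSE)
  m[p$universe]
}

.check_same_universe <- function(partitions, context = "this analysis") {
  u <- partitions[[1]]$universe
  for (p in partitions[-1]) {
    if (!identical(p$universe, u)) {
      missing <- setdiff(u, p$universe)
      extra <- setdiff(p$universe, u)
      stop(sprintf(paste0(
        "universe mismatch between '%s' and '%s': %s requires all markers ",
        "to be delineated from the same set of individuals ",
        "(absent: %s; extraneous: %s). ",
        "Use restrict_to_common = TRUE to intersect universes."),
        partitions[[1]]$label, p$label, context,
        if (length(missing)) paste(missing, collapse = ", ") else "none",
        if (length(extra)) paste(extra, collapse = ", ") else "none"),
        call. = FALSE)
    }
  }
  invisible(u)
}

#' Restrict a partition to a subset of its universe
#'
#' Drops individuals outside `ids` from every block; empty blocks vanish.
#' @param p a `partition`.
#' @param ids individuals to keep.
#' @return a `partition` over `intersect(p$universe, ids)`.
#' @export
restrict_partition <- function(p, ids) {
  stopifnot(inherits(p, "partition"))
  kept <- lapply(p$blocks, intersect, as.character(ids))
  kept <- kept[lengths(kept) > 0L]
  if (length(kept) == 0L) stop("restriction leaves no individuals")
  new_partition(kept, label = p$label)
}

#' Write partitions to a TSV file
#'
#' One row per (partition, block, member is collapsed): columns
#' `marker`, `block_index`, `block_size`, `members` (comma-separated).
#' @param partitions a `partition` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partitions, path) {
  if (inherits(partitions, "partition")) partitions <- list(partitions)
  rows <- do.call(rbind, lapply(partitions, function(p) {
    data.frame(marker = p$label,
               block_index = seq_len(p$k),
               block_size = lengths(p$blocks),
               members = vapply(p$blocks, paste, character(1), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
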