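#' Multi-marker species delimitation
#'
#' The top-level analysis: derives each marker's partition (sl-FFRs for
#' diploid markers, haplogroups for haploid ones), scores all supported
#' bipartitions, computes the multilocus-FFR join and the common
#' refinement meet, and reconciles at the support threshold. This is the
#' whole congruence workflow in one call; each stage remains available
#' as an exported function.
#'
#' @param datasets either a named list of `list(table, dataset)` pairs
#'   (as produced by the readers or the simulator), or a list of
#'   `partition` objects if delineation already happened upstream.
#' @param threshold support-fraction cutoff for [reconcile()];
#'   default 0.5.
#' @param restrict_to_common passed to [score_bipartitions()].
#' @return an object of class `delimitation`: list with `partitions`
#'   (per-marker), `support` (the `support_table`), `join` (ml-FFR
#'   partition over the diploid markers, or all markers if none are
#'   diploid), `meet`, `reconciliation` and `threshold`.
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 7))
#' d <- delimit(sim$datasets)
#' d$reconciliation$partition$k
#' @export
delimit <- function(datasets, threshold = 0.5, restrict_to_common = FALSE) {
  stopifnot(length(datasets) >= 1L)
  partitions <- lapply(datasets, function(d) {
    if (inherits(d, "partition")) d
    else marker_partition(d$dataset)
  })
  support <- score_bipartitions(partitions,
                                restrict_to_common = restrict_to_common)
  if (restrict_to_common) {
    common <- Reduce(intersect, lapply(partitions, `[[`, "universe"))
    partitions <- lapply(partitions, restrict_partition, ids = common)
  }
  diploid <- vapply(datasets, function(d)
    !inherits(d, "partition") && d$dataset$ploidy == 2L, logical(1))
  join_set <- if (any(diploid)) partitions[diploid] else partitions
  structure(list(partitions = partitions,
                 support = support,
                 join = ml_ffr_join(join_set),
                 meet = partition_meet(partitions),
                 reconciliation = reconcile(support, threshold = threshold),
                 threshold = threshold),
            class = "delimitation")
}

#' @export
print.delimitation <- function(x, ...) {
  cat(sprintf("Species delimitation over %d markers: %s\n",
              length(x$partitions),
              paste(sprintf("%s (k=%d)",
                            vapply(x$partitions, `[[`, character(1), "label"),
                            vapply(x$partitions, `[[`, integer(1), "k")),
                    collapse = ", ")))
  cat(sprintf("Supported bipartitions: %d; ml-FFR join: %d block%s (%s); meet: %d block%s (%s)\n",
              nrow(x$support), x$join$k, if (x$join$k == 1L) "" else "s",
              paste(block_sizes(x$join), collapse = "/"),
              x$meet$k, if (x$meet$k == 1L) "" else "s",
              paste(block_sizes(x$meet), collapse = "/")))
  print(x$reconciliation)
  invisible(x)
}

#' @export
summary.delimitation <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$support)
  invisible(object)
}
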