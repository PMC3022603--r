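#' The Clipperton Pocillopora worked example
#'
#' The method's published worked example: 74 coral colonies sampled
#' around Clipperton Island and genotyped at two nuclear markers (ITS2,
#' ATPSbeta intron) and one concatenated mitochondrial marker (ORF +
#' putative control region). The partitions reconstructed here follow
#' the published block structure exactly:
#'
#' * ITS2 sl-FFRs of sizes 55, 17, 1 and 1, the singletons being
#'   05Clip016 and 05Clip056;
#' * ATPSbeta sl-FFRs of sizes 57 and 17;
#' * mitochondrial haplogroups of sizes 52, 17, 3 and 2, the small
#'   groups being \{05Clip027, 05Clip051, 05Clip100\} and \{05Clip048,
#'   05Clip056\};
#' * one 17-individual group (species B) common to all three markers.
#'
#' The published record names the six individuals above but not the
#' membership of the 17-individual group; it is taken here as the 17
#' lexicographically smallest sample names not among those six. Every
#' quantity derived from these partitions (bipartition counts, support
#' percentages, join and meet block sizes) is invariant under renaming
#' of individuals, so this arbitrary choice is immaterial — a property
#' the test suite asserts directly.
#'
#' @return `clipperton_samples()`: character vector of the 74 sample
#'   names. `clipperton_partitions()`: named list of three `partition`
#'   objects (`ITS2`, `ATPSb`, `mito`) over those samples.
#' @examples
#' parts <- clipperton_partitions()
#' sapply(parts, function(p) p$k)
#' @export
clipperton_samples <- function() {
  nums <- c(1:3, 5:7, 12:16, 18, 19, 21, 22, 26:53, 55:64, 79:82, 85:87,
            89, 90, 92:103)
  sprintf("05Clip%03d", nums)
}

#' @rdname clipperton_samples
#' @export
clipperton_partitions <- function() {
  samples <- clipperton_samples()
  named <- c("05Clip016", "05Clip027", "05Clip048", "05Clip051",
             "05Clip056", "05Clip100")
  species_b <- sort(setdiff(samples, named))[1:17]
  rest <- setdiff(samples, species_b)

  its <- new_partition(list(setdiff(rest, c("05Clip016", "05Clip056")),
                            species_b, "05Clip016", "05Clip056"),
                       universe = samples, label = "ITS2")
  atps <- new_partition(list(rest, species_b),
                        universe = samples, label = "ATPSb")
  mito_small2 <- c("05Clip048", "05Clip056")
  mito_small3 <- c("05Clip027", "05Clip051", "05Clip100")
  mito <- new_partition(list(setdiff(rest, c(mito_small2, mito_small3)),
                             species_b, mito_small3, mito_small2),
                        universe = samples, label = "mito")
  list(ITS2 = its, ATPSb = atps, mito = mito)
}
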