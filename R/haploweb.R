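#' Haplowebs, allele pools and fields for recombination
#'
#' A haploweb overlays a haplonet with *co-occurrence links*: one curve
#' per pair of haplotypes found together in a heterozygous individual,
#' weighted by the number of such heterozygotes. Chains of co-occurrence
#' (plus allele sharing through homozygotes) connect haplotypes into
#' *allele pools*; the individuals whose alleles belong to one pool form
#' a single-locus field for recombination (sl-FFR). Groups of
#' individuals in different sl-FFRs share no allele at the marker —
#' mutual allelic exclusivity, the species criterion this method rests
#' on. Pools are computed from co-occurrence and allele sharing only:
#' network edges (including median vectors, which are not alleles of any
#' individual) never merge pools.
#'
#' @name webffr
NULL

#' Co-occurrence links of a diploid marker
#'
#' One link per unordered pair of distinct haplotypes observed together
#' in at least one heterozygote; `weight` counts those heterozygotes.
#' Homozygotes contribute no links.
#'
#' @param ds a `marker_dataset` with ploidy 2.
#' @return data.frame with columns `hap_u`, `hap_v` (with `hap_u <
#'   hap_v`), `weight`; zero rows when every individual is homozygous.
#' @export
cooccurrence_links <- function(ds) {
  stopifnot(inherits(ds, "marker_dataset"))
  if (ds$ploidy != 2L)
    stop("co-occurrence links are defined for diploid markers only; ",
         "use haplogroups() for haploid data")
  het <- Filter(function(g) g[1] != g[2], ds$genotypes)
  if (length(het) == 0L)
    return(data.frame(hap_u = character(0), hap_v = character(0),
                      weight = integer(0), stringsAsFactors = FALSE))
  keys <- vapply(het, function(g) paste(sort(g), collapse = "\x1f"),
                 character(1))
  tb <- table(keys)
  parts <- strsplit(names(tb), "\x1f", fixed = TRUE)
  out <- data.frame(hap_u = vapply(parts, `[`, character(1), 1L),
                    hap_v = vapply(parts, `[`, character(1), 2L),
                    weight = as.integer(tb), stringsAsFactors = FALSE)
  out[order(out$hap_u, out$hap_v), , drop = FALSE]
}

#' Allele pools of a diploid marker
#'
#' Pools are the connected components of the graph whose vertices are
#' all haplotypes of the dataset and whose edges are the co-occurrence
#' links. A haplotype carried only by homozygotes, never co-occurring
#' with another, forms its own singleton pool.
#'
#' @param ds a `marker_dataset` with ploidy 2.
#' @return a `partition` of hap_ids, labelled after the marker.
#' @export
allele_pools <- function(ds) {
  links <- cooccurrence_links(ds)
  haps <- sort(unique(unlist(ds$genotypes, use.names = FALSE)))
  g <- igraph::make_empty_graph(n = length(haps), directed = FALSE)
  igraph::V(g)$name <- haps
  if (nrow(links) > 0L)
    g <- igraph::add_edges(g, rbind(match(links$hap_u, haps),
                                    match(links$hap_v, haps)))
  comp <- igraph::components(g)$membership
  partition_from_membership(haps, comp, label = ds$marker)
}

#' Delineate single-locus FFRs
#'
#' Maps every individual to the allele pool containing its alleles (both
#' alleles of an individual lie in one pool by construction, since a
#' heterozygote's alleles are linked). Equivalently: connected components
#' of the bipartite individual-haplotype sharing graph. Individuals in
#' different blocks share no haplotype.
#'
#' @param ds a `marker_dataset` with ploidy 2.
#' @return a `partition` of individuals, labelled after the marker.
#' @export
delineate_sl_ffrs <- function(ds) {
  pools <- allele_pools(ds)
  pool_of <- .partition_membership(pools)
  assignment <- vapply(ds$genotypes, function(g) pool_of[[g[1]]], integer(1))
  partition_from_membership(ds$universe, assignment[ds$universe],
                            label = ds$marker)
}

#' Sort a haploid marker into haplogroups
#'
#' Individuals carrying the same haplotype form one haplogroup; no
#' distance-based merging is performed, so haplotypes one mutation apart
#' found in different individuals still yield separate haplogroups.
#'
#' @param ds a `marker_dataset` with ploidy 1.
#' @return a `partition` of individuals, labelled after the marker.
#' @export
haplogroups <- function(ds) {
  stopifnot(inherits(ds, "marker_dataset"))
  if (ds$ploidy != 1L)
    stop("haplogroups are defined for haploid markers; ",
         "use delineate_sl_ffrs() for diploid data")
  hap <- vapply(ds$genotypes, `[`, character(1), 1L)
  partition_from_membership(ds$universe, hap[ds$universe], label = ds$marker)
}

#' Marker partition, dispatched on ploidy
#'
#' [delineate_sl_ffrs()] for a diploid dataset, [haplogroups()] for a
#' haploid one.
#' @param ds a `marker_dataset`.
#' @return a `partition` of individuals.
#' @export
marker_partition <- function(ds) {
  if (ds$ploidy == 2L) delineate_sl_ffrs(ds) else haplogroups(ds)
}

#' Assemble a haploweb from its parts
#'
#' Attaches co-occurrence links and the allele-pool assignment to a
#' haplonet, checking referential integrity (every link endpoint and
#' pooled haplotype must be an observed node).
#'
#' @param net a `haplonet` (from [build_mjn()] or [build_msn()]).
#' @param links co-occurrence links, as from [cooccurrence_links()].
#' @param pools `partition` of hap_ids, as from [allele_pools()].
#' @param ffr optional `partition` of individuals (attached for
#'   reporting).
#' @return an object of class `haploweb`.
#' @export
build_haploweb <- function(net, links, pools, ffr = NULL) {
  stopifnot(inherits(net, "haplonet"), inherits(pools, "partition"))
  observed <- net$nodes$hap_id[net$nodes$kind == "observed"]
  dangling <- setdiff(unique(c(links$hap_u, links$hap_v)), observed)
  if (length(dangling) > 0L)
    stop("co-occurrence links reference haplotypes absent from the network: ",
         paste(dangling, collapse = ", "))
  dangling <- setdiff(pools$universe, observed)
  if (length(dangling) > 0L)
    stop("allele pools reference haplotypes absent from the network: ",
         paste(dangling, collapse = ", "))
  pool_of <- .partition_membership(pools)
  net$nodes$pool <- ifelse(net$nodes$kind == "observed",
                           pool_of[net$nodes$hap_id], NA_integer_)
  structure(list(net = net, links = links, pools = pools, ffr = ffr),
            class = "haploweb")
}

#' Build a haploweb for one diploid marker
#'
#' The one-stop constructor: collapses nothing (input is already a
#' haplotype table + dataset), builds the median-joining network,
#' derives co-occurrence links, allele pools and the sl-FFR partition,
#' and assembles the annotated haploweb.
#'
#' @param table a `haplotype_table`.
#' @param ds the companion `marker_dataset` (ploidy 2).
#' @param epsilon median-joining relaxation parameter; default 0.
#' @param gap_mode see [mutation_distance()].
#' @param network `"mjn"` (default) or `"msn"`.
#' @return a `haploweb` with the sl-FFR partition attached as `$ffr`.
#' @examples
#' recs <- data.frame(seq_id = c("I1_a", "I1_b", "I2_a", "I2_b"),
#'                    individual_id = c("I1", "I1", "I2", "I2"),
#'                    marker = "toy",
#'                    sequence = c("ACG", "ACT", "ACG", "ACG"))
#' x <- collapse_haplotypes(recs, ploidy = 2)
#' hw <- haploweb(x$table, x$dataset)
#' hw$ffr
#' @export
haploweb <- function(table, ds, epsilon = 0L,
                     gap_mode = c("fifth_state", "ignore"),
                     network = c("mjn", "msn")) {
  gap_mode <- match.arg(gap_mode)
  network <- match.arg(network)
  stopifnot(inherits(ds, "marker_dataset"), ds$ploidy == 2L)
  net <- if (network == "mjn") build_mjn(table, epsilon = epsilon,
                                         gap_mode = gap_mode)
  else build_msn(table, gap_mode = gap_mode, epsilon = epsilon)
  links <- cooccurrence_links(ds)
  pools <- allele_pools(ds)
  build_haploweb(net, links, pools, ffr = delineate_sl_ffrs(ds))
}

#' @export
print.haploweb <- function(x, ...) {
  print(x$net)
  cat(sprintf("Co-occurrence links: %d (from %d heterozygote%s); allele pools: %d\n",
              nrow(x$links), sum(x$links$weight),
              if (sum(x$links$weight) == 1L) "" else "s", x$pools$k))
  if (!is.null(x$ffr))
    cat(sprintf("sl-FFRs: %d block%s of sizes %s\n", x$ffr$k,
                if (x$ffr$k == 1L) "" else "s",
                paste(block_sizes(x$ffr), collapse = ", ")))
  invisible(x)
}

#' @export
summary.haploweb <- function(object, ...) {
  print(object)
  cat("\nAllele pools:\n")
  print(object$pools)
  invisible(object)
}

#' Plot a haploweb
#'
#' Base-graphics rendering with the conventional encodings: circle
#' diameter proportional to haplotype count, co-occurrence curves with
#' width proportional to heterozygote count, dashed hulls around allele
#' pools, median vectors as small grey points.
#'
#' @param x a `haploweb` or `haplonet`.
#' @param layout_seed seed for the force-directed layout.
#' @param ... ignored.
#' @return invisibly, the layout coordinates.
#' @export
plot.haploweb <- function(x, layout_seed = 42L, ...) {
  net <- x$net
  coords <- .layout_coords(net, layout_seed)
  obs <- net$nodes$kind == "observed"
  plot(coords, type = "n", axes = FALSE, xlab = "", ylab = "",
       main = "haploweb")
  for (i in seq_len(nrow(net$edges))) {
    a <- match(net$edges$from[i], net$nodes$node_id)
    b <- match(net$edges$to[i], net$nodes$node_id)
    graphics::segments(coords[a, 1], coords[a, 2], coords[b, 1], coords[b, 2],
                       col = "grey40")
  }
  if (nrow(x$links) > 0L) for (i in seq_len(nrow(x$links))) {
    a <- match(x$links$hap_u[i], net$nodes$node_id)
    b <- match(x$links$hap_v[i], net$nodes$node_id)
    graphics::lines(.bezier(coords[a, ], coords[b, ]), col = "forestgreen",
                    lwd = x$links$weight[i])
  }
  graphics::points(coords[!obs, , drop = FALSE], pch = 16, cex = 0.5,
                   col = "grey60")
  graphics::symbols(coords[obs, 1], coords[obs, 2],
                    circles = 0.02 + 0.02 * sqrt(net$nodes$count[obs]),
                    inches = FALSE, add = TRUE, bg = "lightsteelblue")
  graphics::text(coords[obs, ], labels = net$nodes$hap_id[obs], cex = 0.7)
  invisible(coords)
}

#' @export
plot.haplonet <- function(x, layout_seed = 42L, ...) {
  plot.haploweb(list(net = x,
                     links = data.frame(hap_u = character(0),
                                        hap_v = character(0),
                                        weight = integer(0))),
                layout_seed = layout_seed, ...)
}

.layout_coords <- function(net, layout_seed) {
  g <- .as_igraph(net)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(layout_seed)
  if (igraph::vcount(g) == 1L) return(matrix(0, 1, 2))
  igraph::layout_with_fr(g)
}

# quadratic Bezier arc between two points, bowed sideways
.bezier <- function(p, q, n = 30L) {
  mid <- (p + q) / 2
  d <- q - p
  ctrl <- mid + 0.25 * c(-d[2], d[1])
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p[1] + 2 * (1 - t) * t * ctrl[1] + t^2 * q[1],
        (1 - t)^2 * p[2] + 2 * (1 - t) * t * ctrl[2] + t^2 * q[2])
}
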