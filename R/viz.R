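#' Graph export and SVG rendering
#'
#' Haplowebs serialize to GraphML and DOT (two edge classes: network
#' edges with mutation length and positions, co-occurrence links with
#' heterozygote weight) and render to SVG with the conventional
#' proportional encodings: node diameter linear in haplotype count,
#' co-occurrence curve width linear in heterozygote count, bipartition
#' stroke width linear in the number of supporting datasets. All
#' renderings are pure functions of (object, style, layout seed):
#' identical inputs give byte-identical SVG.
#'
#' @name viz_export
NULL

#' Style parameters for SVG rendering
#'
#' @param diameter_per_count px of node diameter per individual carrying
#'   the haplotype (the diameter, not the area, is linear in count;
#'   set `scale = "area"` for perceptual area scaling).
#' @param min_diameter,max_diameter clamp for node diameters (px).
#' @param curve_width_per_heterozygote px of co-occurrence curve stroke
#'   per heterozygote.
#' @param bipartition_line_width_per_dataset px of bipartition stroke
#'   per supporting dataset.
#' @param pool_dash SVG dash pattern for allele-pool outlines.
#' @param layout_seed seed for the force-directed layout.
#' @param scale `"diameter"` (default) or `"area"`.
#' @return a `style_spec` list.
#' @export
style_spec <- function(diameter_per_count = 6, min_diameter = 6,
                       max_diameter = 60, curve_width_per_heterozygote = 1.5,
                       bipartition_line_width_per_dataset = 2,
                       pool_dash = "6,4", layout_seed = 42L,
                       scale = c("diameter", "area")) {
  scale <- match.arg(scale)
  stopifnot(diameter_per_count > 0, min_diameter > 0,
            max_diameter >= min_diameter, curve_width_per_heterozygote > 0,
            bipartition_line_width_per_dataset > 0)
  structure(list(diameter_per_count = diameter_per_count,
                 min_diameter = min_diameter, max_diameter = max_diameter,
                 curve_width_per_heterozygote = curve_width_per_heterozygote,
                 bipartition_line_width_per_dataset =
                   bipartition_line_width_per_dataset,
                 pool_dash = pool_dash, layout_seed = as.integer(layout_seed),
                 scale = scale), class = "style_spec")
}

#' Export a haploweb as GraphML or DOT
#'
#' Node attributes: `name` (node id), `kind` (observed/median), `count`,
#' `pool`; edge attributes: `class` (network/cooccurrence), `length`,
#' `positions` (comma-separated alignment columns), `weight`.
#'
#' @param web a `haploweb`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(web, path) {
  igraph::write_graph(.haploweb_igraph(web), path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
export_dot <- function(web, path) {
  igraph::write_graph(.haploweb_igraph(web), path, format = "dot")
  invisible(path)
}

.haploweb_igraph <- function(web) {
  stopifnot(inherits(web, "haploweb"))
  g <- .as_igraph(web$net, links = web$links)
  pool <- web$net$nodes$pool
  igraph::V(g)$pool <- ifelse(is.na(pool), -1L, pool)
  if (igraph::ecount(g) > 0L) {
    igraph::E(g)$length[is.na(igraph::E(g)$length)] <- -1L
    igraph::E(g)$weight[is.na(igraph::E(g)$weight)] <- -1L
    igraph::E(g)$positions[is.na(igraph::E(g)$positions)] <- ""
  }
  g
}

.fmt <- function(x) formatC(x, format = "f", digits = 2)

.svg_open <- function(w, h) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            w, h, w, h),
    '<rect width="100%" height="100%" fill="white"/>')
}

# scale layout coordinates into a margin-padded canvas
.fit_canvas <- function(coords, w, h, margin) {
  if (nrow(coords) == 1L) return(matrix(c(w / 2, h / 2), 1, 2))
  rng_x <- range(coords[, 1]); rng_y <- range(coords[, 2])
  sx <- if (diff(rng_x) > 0) (w - 2 * margin) / diff(rng_x) else 0
  sy <- if (diff(rng_y) > 0) (h - 2 * margin) / diff(rng_y) else 0
  cbind(margin + (coords[, 1] - rng_x[1]) * sx,
        margin + (coords[, 2] - rng_y[1]) * sy)
}

#' Render a haploweb as SVG
#'
#' Network edges as straight lines labelled with their mutated
#' positions; co-occurrence links as quadratic Bezier curves with stroke
#' width `curve_width_per_heterozygote * weight`; each allele pool
#' enclosed by a dashed convex hull; median vectors as small unlabelled
#' points; observed nodes as circles with diameter
#' `diameter_per_count * count`, clamped to the style's limits.
#'
#' @param web a `haploweb`.
#' @param path optional output file; when NULL the SVG is only returned.
#' @param style a [style_spec()].
#' @param width,height canvas size in px.
#' @return the SVG document as a character string (invisibly when
#'   `path` is given).
#' @export
render_haploweb_svg <- function(web, path = NULL, style = style_spec(),
                                width = 800L, height = 600L) {
  stopifnot(inherits(web, "haploweb"), inherits(style, "style_spec"))
  net <- web$net
  coords <- .fit_canvas(.layout_coords(net, style$layout_seed),
                        width, height, margin = 60)
  id_of <- stats::setNames(seq_len(nrow(net$nodes)), net$nodes$node_id)
  obs <- net$nodes$kind == "observed"
  lines <- .svg_open(width, height)

  for (i in seq_len(nrow(net$edges))) {
    a <- coords[id_of[[net$edges$from[i]]], ]
    b <- coords[id_of[[net$edges$to[i]]], ]
    lines <- c(lines, sprintf(
      '<line class="net-edge" x1="%s" y1="%s" x2="%s" y2="%s" stroke="grey" stroke-width="1"/>',
      .fmt(a[1]), .fmt(a[2]), .fmt(b[1]), .fmt(b[2])))
    pos <- net$edges$positions[[i]]
    if (length(pos) > 0L)
      lines <- c(lines, sprintf(
        '<text class="edge-label" x="%s" y="%s" font-size="8" fill="firebrick">%s</text>',
        .fmt((a[1] + b[1]) / 2), .fmt((a[2] + b[2]) / 2),
        paste(pos, collapse = " ")))
  }
  if (nrow(web$links) > 0L) for (i in seq_len(nrow(web$links))) {
    a <- coords[id_of[[web$links$hap_u[i]]], ]
    b <- coords[id_of[[web$links$hap_v[i]]], ]
    mid <- (a + b) / 2
    ctrl <- mid + 0.25 * c(-(b - a)[2], (b - a)[1])
    lines <- c(lines, sprintf(
      '<path class="cooc-link" d="M %s %s Q %s %s %s %s" fill="none" stroke="forestgreen" stroke-width="%s" opacity="0.7"/>',
      .fmt(a[1]), .fmt(a[2]), .fmt(ctrl[1]), .fmt(ctrl[2]),
      .fmt(b[1]), .fmt(b[2]),
      .fmt(style$curve_width_per_heterozygote * web$links$weight[i])))
  }
  # dashed hull around each pool with >= 1 member node
  pool_ids <- sort(unique(stats::na.omit(net$nodes$pool)))
  for (p in pool_ids) {
    members <- which(!is.na(net$nodes$pool) & net$nodes$pool == p)
    pts <- coords[members, , drop = FALSE]
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    pad <- 18
    cx <- mean(hull[, 1]); cy <- mean(hull[, 2])
    hull <- cbind(cx + (hull[, 1] - cx) * 1.15 +
                    pad * sign(hull[, 1] - cx),
                  cy + (hull[, 2] - cy) * 1.15 + pad * sign(hull[, 2] - cy))
    lines <- c(lines, sprintf(
      '<polygon class="pool-outline" points="%s" fill="none" stroke="seagreen" stroke-dasharray="%s"/>',
      paste(sprintf("%s,%s", .fmt(hull[, 1]), .fmt(hull[, 2])),
            collapse = " "), style$pool_dash))
  }
  for (i in which(!obs))
    lines <- c(lines, sprintf(
      '<circle class="median-vector" cx="%s" cy="%s" r="2.5" fill="grey"/>',
      .fmt(coords[i, 1]), .fmt(coords[i, 2])))
  for (i in which(obs)) {
    d <- if (style$scale == "diameter")
      style$diameter_per_count * net$nodes$count[i]
    else 2 * sqrt(style$diameter_per_count^2 * net$nodes$count[i] / pi)
    d <- min(max(d, style$min_diameter), style$max_diameter)
    lines <- c(lines, sprintf(
      '<circle class="haplotype" cx="%s" cy="%s" r="%s" fill="lightsteelblue" stroke="black" data-count="%d"/>',
      .fmt(coords[i, 1]), .fmt(coords[i, 2]), .fmt(d / 2),
      net$nodes$count[i]),
      sprintf('<text x="%s" y="%s" font-size="10" text-anchor="middle">%s</text>',
              .fmt(coords[i, 1]), .fmt(coords[i, 2] + 3),
              net$nodes$hap_id[i]))
  }
  svg <- paste(c(lines, "</svg>"), collapse = "\n")
  if (!is.null(path)) { writeLines(svg, path); return(invisible(svg)) }
  svg
}

#' Render a bipartition reconciliation as SVG
#'
#' Individuals are laid out in clusters, one per block of the meet of
#' the input partitions (the finest regions no marker ever splits);
#' each bipartition at or above the display threshold is drawn as a
#' closed curve around its canonical side with stroke width
#' `bipartition_line_width_per_dataset * n_support`, labelled with its
#' row number in the table.
#'
#' @param table a [score_bipartitions()] result.
#' @param partitions the scored partitions (used for the meet layout).
#' @param path optional output file.
#' @param style a [style_spec()].
#' @param threshold optional support fraction: rows with support at or
#'   below it are omitted (the de-cluttered variant).
#' @param width,height canvas size in px.
#' @return the SVG document string (invisibly when `path` is given).
#' @export
render_reconciliation_svg <- function(table, partitions, path = NULL,
                                      style = style_spec(),
                                      threshold = NULL,
                                      width = 900L, height = 700L) {
  stopifnot(inherits(table, "support_table"))
  meet <- partition_meet(partitions)
  universe <- attr(table, "universe")
  # cluster centres on a grid, individuals on sub-grids inside
  kb <- meet$k
  ncol_g <- ceiling(sqrt(kb))
  nrow_g <- ceiling(kb / ncol_g)
  coords <- matrix(NA_real_, length(universe), 2,
                   dimnames = list(universe, NULL))
  cw <- (width - 120) / ncol_g
  ch <- (height - 120) / nrow_g
  for (b in seq_len(kb)) {
    gx <- (b - 1L) %% ncol_g
    gy <- (b - 1L) %/% ncol_g
    members <- meet$blocks[[b]]
    nc <- ceiling(sqrt(length(members)))
    for (j in seq_along(members)) {
      jx <- (j - 1L) %% nc; jy <- (j - 1L) %/% nc
      coords[members[j], ] <- c(
        60 + gx * cw + cw * 0.2 + jx * min(14, cw * 0.6 / nc),
        60 + gy * ch + ch * 0.2 + jy * min(14, ch * 0.6 / nc))
    }
  }
  rows <- seq_len(nrow(table))
  if (!is.null(threshold)) rows <- rows[table$support > threshold]
  lines <- .svg_open(width, height)
  for (i in rows) {
    side <- table$side[[i]]
    pts <- coords[side, , drop = FALSE]
    cx <- mean(pts[, 1]); cy <- mean(pts[, 2])
    rx <- max(max(abs(pts[, 1] - cx)), 6) + 14 + 2 * i
    ry <- max(max(abs(pts[, 2] - cy)), 6) + 14 + 2 * i
    w <- style$bipartition_line_width_per_dataset * table$n_support[i]
    lines <- c(lines, sprintf(
      '<ellipse class="bipartition" data-row="%d" cx="%s" cy="%s" rx="%s" ry="%s" fill="none" stroke="steelblue" stroke-width="%s"/>',
      i, .fmt(cx), .fmt(cy), .fmt(rx), .fmt(ry), .fmt(w)),
      sprintf('<text x="%s" y="%s" font-size="10" fill="steelblue">%d</text>',
              .fmt(cx + rx - 6), .fmt(cy - ry + 10), i))
  }
  for (ind in universe)
    lines <- c(lines,
               sprintf('<circle class="individual" cx="%s" cy="%s" r="2" fill="black"/>',
                       .fmt(coords[ind, 1]), .fmt(coords[ind, 2])))
  svg <- paste(c(lines, "</svg>"), collapse = "\n")
  if (!is.null(path)) { writeLines(svg, path); return(invisible(svg)) }
  svg
}
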