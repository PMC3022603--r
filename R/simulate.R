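#' Simulated multi-marker datasets with known species truth
#'
#' The generator realises the regime the delimitation criterion targets:
#' several reproductively isolated species whose allele pools are
#' mutually exclusive at every marker but need not be reciprocally
#' monophyletic. Each species' pool descends from a species ancestor by
#' a star genealogy (independent mutations per haplotype, sampled
#' without replacement, so no back-mutation and all intra-pool distances
#' are closed-form); species ancestors are separated by disjoint blocks
#' of mutated positions, guaranteeing pool disjointness by construction.
#' Diploid genotypes are two independent draws from the species' allele
#' frequency distribution (Hardy-Weinberg); haploid markers get one
#' draw. Anomaly injection reproduces the known failure modes: F1
#' hybrids, single-marker introgression and shared ancestral haplotypes.
#'
#' @name simulate
NULL

#' Simulation configuration
#'
#' @param n_species number of reproductively isolated species.
#' @param individuals_per_species sampled individuals per species
#'   (recycled to `n_species`).
#' @param markers named integer vector of ploidies (1 or 2), one entry
#'   per marker. Default: two diploid nuclear markers and one haploid
#'   organelle-like marker.
#' @param seq_length alignment length per marker (bp).
#' @param intra_haplotypes haplotypes per species per marker.
#' @param intra_mutations mutations separating each haplotype from its
#'   species ancestor.
#' @param inter_mutations mutations separating each species ancestor
#'   from the root; species get disjoint mutated position blocks, so
#'   ancestors are pairwise `2 * inter_mutations` apart. Must exceed
#'   `2 * intra_mutations` so pools cannot merge by homoplasy.
#' @param allele_freq_concentration Dirichlet concentration for the
#'   allele frequencies of each pool (1 = uniform on the simplex;
#'   smaller = more skewed, one common + several rare haplotypes).
#' @param f1_hybrid_count,introgressed_allele_count,shared_ancestral_count
#'   anomaly counts applied by [inject_anomalies()].
#' @param introgression_marker marker (name) receiving the introgressed
#'   alleles; defaults to the first diploid marker.
#' @param seed RNG seed; the entire dataset is a deterministic function
#'   of the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 2L, individuals_per_species = 20L,
                       markers = c(nuc1 = 2L, nuc2 = 2L, mito = 1L),
                       seq_length = 300L, intra_haplotypes = 4L,
                       intra_mutations = 2L, inter_mutations = 20L,
                       allele_freq_concentration = 1,
                       f1_hybrid_count = 0L, introgressed_allele_count = 0L,
                       shared_ancestral_count = 0L,
                       introgression_marker = NULL, seed = 1L) {
  stopifnot(n_species >= 1L, all(individuals_per_species >= 1L),
            length(markers) >= 1L, !is.null(names(markers)),
            all(markers %in% c(1L, 2L)), intra_haplotypes >= 1L,
            intra_mutations >= 0L, allele_freq_concentration > 0)
  if (n_species > 1L && inter_mutations < 2L * intra_mutations + 1L)
    stop(sprintf(paste0("inter_mutations (%d) must be at least ",
                        "2*intra_mutations + 1 = %d to guarantee exclusive pools"),
                 inter_mutations, 2L * intra_mutations + 1L))
  need <- n_species * inter_mutations +
    intra_haplotypes * intra_mutations
  if (seq_length < need)
    stop(sprintf("seq_length = %d is too short to host %d species x %d inter + %d x %d intra mutations (need >= %d)",
                 seq_length, n_species, inter_mutations, intra_haplotypes,
                 intra_mutations, need))
  if (is.null(introgression_marker)) {
    dip <- names(markers)[markers == 2L]
    introgression_marker <- if (length(dip)) dip[1] else names(markers)[1]
  }
  structure(list(
    n_species = as.integer(n_species),
    individuals_per_species = rep_len(as.integer(individuals_per_species),
                                      n_species),
    markers = markers, seq_length = as.integer(seq_length),
    intra_haplotypes = as.integer(intra_haplotypes),
    intra_mutations = as.integer(intra_mutations),
    inter_mutations = as.integer(inter_mutations),
    allele_freq_concentration = allele_freq_concentration,
    f1_hybrid_count = as.integer(f1_hybrid_count),
    introgressed_allele_count = as.integer(introgressed_allele_count),
    shared_ancestral_count = as.integer(shared_ancestral_count),
    introgression_marker = introgression_marker,
    seed = as.integer(seed)), class = "sim_config")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.rdirichlet1 <- function(k, conc) {
  x <- stats::rgamma(k, shape = conc)
  while (sum(x) == 0) x <- stats::rgamma(k, shape = conc)
  x / sum(x)
}

.mutate <- function(seq_chars, positions) {
  bases <- c("A", "C", "G", "T")
  for (p in positions) {
    seq_chars[p] <- sample(setdiff(bases, seq_chars[p]), 1L)
  }
  seq_chars
}

#' Simulate a multi-marker dataset
#'
#' @param cfg a [sim_config()].
#' @return list with `datasets` (named list per marker of
#'   `list(table, dataset)`), `truth` (species `partition`, label
#'   "truth"), `pools` (per marker, per species, the haplotype sequences
#'   of each pool) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    bases <- c("A", "C", "G", "T")
    n_sp <- cfg$n_species
    ids <- unlist(lapply(seq_len(n_sp), function(s)
      sprintf("sp%d_i%02d", s, seq_len(cfg$individuals_per_species[s]))))
    species_of <- rep(seq_len(n_sp), cfg$individuals_per_species)
    names(species_of) <- ids
    truth <- partition_from_membership(ids, species_of, label = "truth")

    datasets <- list()
    pools <- list()
    for (m in names(cfg$markers)) {
      ploidy <- cfg$markers[[m]]
      root <- sample(bases, cfg$seq_length, replace = TRUE)
      # disjoint inter-species position blocks -> ancestors pairwise
      # 2*inter_mutations apart
      inter_pos <- sample(cfg$seq_length, n_sp * cfg$inter_mutations)
      marker_pools <- list()
      for (s in seq_len(n_sp)) {
        anc <- .mutate(root, inter_pos[seq_len(cfg$inter_mutations) +
                                         (s - 1L) * cfg$inter_mutations])
        avail <- setdiff(seq_len(cfg$seq_length), inter_pos)
        haps <- character(0)
        guard <- 0L
        while (length(haps) < cfg$intra_haplotypes) {
          guard <- guard + 1L
          if (guard > 100L * cfg$intra_haplotypes)
            stop("could not generate enough distinct haplotypes; increase seq_length")
          h <- paste(.mutate(anc, if (cfg$intra_mutations > 0L)
            sample(avail, cfg$intra_mutations) else integer(0)), collapse = "")
          if (!(h %in% haps)) haps <- c(haps, h)
          if (cfg$intra_mutations == 0L) break
        }
        marker_pools[[s]] <- haps
      }
      # exclusivity is guaranteed by construction; assert anyway
      for (s1 in seq_len(n_sp)) for (s2 in seq_len(n_sp)) {
        if (s1 < s2 && length(intersect(marker_pools[[s1]],
                                        marker_pools[[s2]])) > 0L)
          stop("internal error: species pools overlap at generation")
      }
      freqs <- lapply(marker_pools, function(p)
        .rdirichlet1(length(p), cfg$allele_freq_concentration))
      seqs <- character(0); seq_ids <- character(0); owners <- character(0)
      for (i in seq_along(ids)) {
        s <- species_of[[ids[i]]]
        draw <- sample(length(marker_pools[[s]]), ploidy, replace = TRUE,
                       prob = freqs[[s]])
        if (ploidy == 2L) {
          seq_ids <- c(seq_ids, paste0(ids[i], "_a"), paste0(ids[i], "_b"))
          seqs <- c(seqs, marker_pools[[s]][draw])
          owners <- c(owners, ids[i], ids[i])
        } else {
          seq_ids <- c(seq_ids, ids[i])
          seqs <- c(seqs, marker_pools[[s]][draw])
          owners <- c(owners, ids[i])
        }
      }
      records <- data.frame(seq_id = seq_ids, individual_id = owners,
                            marker = m, sequence = seqs,
                            stringsAsFactors = FALSE)
      datasets[[m]] <- suppressMessages(
        collapse_haplotypes(records, ploidy = ploidy))
      pools[[m]] <- marker_pools
    }
    out <- list(datasets = datasets, truth = truth, pools = pools,
                config = cfg)
    class(out) <- "haploweb_sim"
    if (cfg$f1_hybrid_count > 0L || cfg$introgressed_allele_count > 0L ||
        cfg$shared_ancestral_count > 0L)
      out <- inject_anomalies(out)
    out
  })
}

#' @export
print.haploweb_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated dataset: %d species, %s individuals, %d markers (%s), seed %d\n",
              cfg$n_species,
              paste(cfg$individuals_per_species, collapse = "+"),
              length(cfg$markers),
              paste(sprintf("%s:%dn", names(cfg$markers), cfg$markers),
                    collapse = ", "), cfg$seed))
  if (!is.null(x$anomalies) && nrow(x$anomalies) > 0L) {
    cat("Anomalies injected:\n")
    print(x$anomalies, row.names = FALSE)
  }
  invisible(x)
}

#' Inject anomalies into a simulated dataset
#'
#' Applies, in order and with counts taken from the config: F1 hybrids
#' (a new individual drawing one allele from each of the first two
#' species' pools at every diploid marker, and its haploid alleles from
#' species 1, the maternal side); introgressed alleles (one allele of
#' one existing species-1 individual at the configured marker replaced
#' by a species-2 haplotype); shared ancestral haplotypes (a species-1
#' haplotype duplicated into species 2's pool at one marker by
#' overwriting one allele of a species-2 individual). All draws come
#' from the simulation's seeded RNG stream, so the result is a
#' deterministic function of the config.
#'
#' @param sim a `haploweb_sim` (called automatically by
#'   [simulate_dataset()] when the config requests anomalies; callable
#'   directly to re-apply with modified counts).
#' @param f1_hybrid_count,introgressed_allele_count,shared_ancestral_count
#'   overrides of the config counts.
#' @return the modified `haploweb_sim`, with an `anomalies` data.frame
#'   describing each event.
#' @export
inject_anomalies <- function(sim, f1_hybrid_count = NULL,
                             introgressed_allele_count = NULL,
                             shared_ancestral_count = NULL) {
  stopifnot(inherits(sim, "haploweb_sim"))
  cfg <- sim$config
  n_f1 <- if (is.null(f1_hybrid_count)) cfg$f1_hybrid_count
  else as.integer(f1_hybrid_count)
  n_intro <- if (is.null(introgressed_allele_count))
    cfg$introgressed_allele_count else as.integer(introgressed_allele_count)
  n_shared <- if (is.null(shared_ancestral_count))
    cfg$shared_ancestral_count else as.integer(shared_ancestral_count)
  if (cfg$n_species < 2L && (n_f1 > 0L || n_intro > 0L || n_shared > 0L))
    stop("anomalies require at least 2 species")

  # work at the sequence level: rebuild records per marker, edit, recollapse
  recs <- lapply(names(sim$datasets), function(m) {
    d <- sim$datasets[[m]]
    seq_of <- stats::setNames(d$table$sequence, d$table$hap_id)
    ds <- d$dataset
    do.call(rbind, lapply(ds$universe, function(ind) {
      g <- ds$genotypes[[ind]]
      if (ds$ploidy == 2L)
        data.frame(seq_id = paste0(ind, c("_a", "_b")), individual_id = ind,
                   marker = m, sequence = unname(seq_of[g]),
                   stringsAsFactors = FALSE)
      else
        data.frame(seq_id = ind, individual_id = ind, marker = m,
                   sequence = unname(seq_of[g[1]]), stringsAsFactors = FALSE)
    }))
  })
  names(recs) <- names(sim$datasets)

  log <- list()
  sp1 <- grep("^sp1_", sim$truth$universe, value = TRUE)
  sp2 <- grep("^sp2_", sim$truth$universe, value = TRUE)

  # an F1 hybrid's alleles are drawn from the parental populations as
  # sampled (frequency-weighted copies), so each allele is shared with its
  # source species
  allele_copies <- function(m, inds)
    recs[[m]]$sequence[recs[[m]]$individual_id %in% inds]

  if (n_f1 > 0L) for (h in seq_len(n_f1)) {
    hyb <- sprintf("hyb_%02d", h)
    for (m in names(recs)) {
      ploidy <- cfg$markers[[m]]
      p1 <- sample(allele_copies(m, sp1), 1L)
      if (ploidy == 2L) {
        p2 <- sample(allele_copies(m, sp2), 1L)
        recs[[m]] <- rbind(recs[[m]], data.frame(
          seq_id = paste0(hyb, c("_a", "_b")), individual_id = hyb,
          marker = m, sequence = c(p1, p2), stringsAsFactors = FALSE))
      } else {
        recs[[m]] <- rbind(recs[[m]], data.frame(
          seq_id = hyb, individual_id = hyb, marker = m, sequence = p1,
          stringsAsFactors = FALSE))
      }
    }
    log[[length(log) + 1L]] <- data.frame(kind = "f1_hybrid", marker = "all",
                                          individual = hyb)
  }

  # a donated haplotype must actually be carried by the donor species'
  # sampled individuals, or the recipient would not join the donor pool
  observed_alleles <- function(m, inds)
    unique(recs[[m]]$sequence[recs[[m]]$individual_id %in% inds])

  if (n_intro > 0L) {
    m <- cfg$introgression_marker
    victims <- sample(sp1, n_intro)
    for (v in victims) {
      donor <- sample(observed_alleles(m, sp2), 1L)
      row <- which(recs[[m]]$individual_id == v)[1]
      recs[[m]]$sequence[row] <- donor
      log[[length(log) + 1L]] <- data.frame(kind = "introgression",
                                            marker = m, individual = v)
    }
  }

  if (n_shared > 0L) {
    m <- cfg$introgression_marker
    victims <- sample(sp2, n_shared)
    for (v in victims) {
      shared <- sample(observed_alleles(m, sp1), 1L)
      row <- which(recs[[m]]$individual_id == v)[1]
      recs[[m]]$sequence[row] <- shared
      log[[length(log) + 1L]] <- data.frame(kind = "shared_ancestral",
                                            marker = m, individual = v)
    }
  }

  sim$datasets <- lapply(names(recs), function(m)
    suppressMessages(collapse_haplotypes(recs[[m]],
                                         ploidy = cfg$markers[[m]])))
  names(sim$datasets) <- names(recs)
  if (n_f1 > 0L) {
    hybs <- sprintf("hyb_%02d", seq_len(n_f1))
    blocks <- sim$truth$blocks
    b1 <- which(vapply(blocks, function(b) sp1[1] %in% b, logical(1)))
    blocks[[b1]] <- c(blocks[[b1]], hybs)  # hybrids filed with species 1
    sim$truth <- new_partition(blocks, label = "truth")
  }
  sim$anomalies <- if (length(log)) do.call(rbind, log)
  else data.frame(kind = character(0), marker = character(0),
                  individual = character(0))
  sim
}

#' Write a simulated dataset to disk
#'
#' Emits one aligned FASTA per marker (the formats the readers accept),
#' the truth partition as TSV, and the config as JSON.
#'
#' @param sim a `haploweb_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(sim$datasets))
    write_phased_fasta(sim$datasets[[m]], file.path(dir, paste0(m, ".fasta")))
  write_partition_tsv(sim$truth, file.path(dir, "truth.tsv"))
  cfg <- sim$config
  cfg$markers <- as.list(cfg$markers)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
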