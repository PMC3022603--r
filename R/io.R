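#' Reading phased alleles and collapsing haplotypes
#'
#' Input is one aligned FASTA per marker containing the phased allele
#' sequences: two sequences per diploid individual (one per allele), one
#' per haploid individual. Identical sequences are collapsed into
#' haplotypes; the result is a haplotype table (the nodes of a haplonet)
#' and a marker dataset mapping each individual to its alleles.
#'
#' @name io_model
NULL

# character-class body for sequence cells; '-' last so it is literal
DNA_CHARS <- "ACGTUNRYSWKMBDHV?-"

.new_haplotype_table <- function(marker, hap_id, sequence, members) {
  stopifnot(length(hap_id) == length(sequence), length(hap_id) == length(members))
  tab <- data.frame(hap_id = hap_id, sequence = sequence,
                    count = vapply(members, length, integer(1)),
                    stringsAsFactors = FALSE)
  tab$members <- lapply(members, function(m) sort(unique(m)))
  structure(tab, marker = marker, class = c("haplotype_table", "data.frame"))
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("Haplotype table for marker '%s': %d haplotypes, %d sequences\n",
              attr(x, "marker"), nrow(x), sum(x$count)))
  df <- data.frame(hap_id = x$hap_id, count = x$count,
                   n_individuals = vapply(x$members, length, integer(1)))
  print(utils::head(df, 15))
  if (nrow(x) > 15L) cat("...\n")
  invisible(x)
}

.new_marker_dataset <- function(marker, ploidy, genotypes, universe) {
  stopifnot(ploidy %in% c(1L, 2L),
            all(lengths(genotypes) == ploidy),
            setequal(names(genotypes), universe))
  structure(list(marker = marker, ploidy = as.integer(ploidy),
                 genotypes = genotypes[universe], universe = universe),
            class = "marker_dataset")
}

#' @export
print.marker_dataset <- function(x, ...) {
  het <- if (x$ploidy == 2L)
    sum(vapply(x$genotypes, function(g) g[1] != g[2], logical(1)))
  else NA_integer_
  cat(sprintf("Marker '%s' (ploidy %d): %d individuals%s\n", x$marker,
              x$ploidy, length(x$universe),
              if (x$ploidy == 2L)
                sprintf(", %d heterozygous / %d homozygous",
                        het, length(x$universe) - het) else ""))
  invisible(x)
}

#' Collapse aligned sequence records into haplotypes
#'
#' Haplotype identity is exact case-insensitive string equality, with the
#' gap character `-` as a fifth state: two sequences differing only in
#' gap placement are distinct haplotypes. Ambiguity codes are matched
#' exactly (no expansion) and trigger a warning. Haplotype ids `h1, h2,
#' ...` are assigned in order of first appearance after sorting records
#' by `seq_id`, so the labelling is stable under record shuffling.
#'
#' @param records data.frame with columns `seq_id`, `individual_id`,
#'   `marker`, `sequence` (equal-length aligned strings).
#' @param ploidy 1 or 2. A diploid individual represented by a single
#'   sequence is taken as an assumed homozygote (its sequence is
#'   duplicated) with a message; more than `ploidy` sequences for one
#'   individual is an error.
#' @param exclude_columns optional integer vector of 1-based alignment
#'   columns to drop before collapsing (the curation hook for
#'   hypervariable regions of uncertain homology).
#' @return list with `table` (a `haplotype_table`) and `dataset`
#'   (a `marker_dataset`).
#' @export
collapse_haplotypes <- function(records, ploidy = 2L, exclude_columns = NULL) {
  ploidy <- as.integer(ploidy)
  stopifnot(is.data.frame(records),
            all(c("seq_id", "individual_id", "marker", "sequence") %in%
                  names(records)),
            nrow(records) > 0L, ploidy %in% c(1L, 2L))
  marker <- records$marker[1]
  records <- records[order(records$seq_id), , drop = FALSE]
  seqs <- toupper(records$sequence)
  if (any(nchar(seqs) == 0L)) stop("empty sequence in records")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop(sprintf("ragged alignment for marker '%s': sequence '%s' has length %d, expected %d",
                 marker, records$seq_id[which(lens != lens[1])[1]],
                 lens[which(lens != lens[1])[1]], lens[1]))
  if (!is.null(exclude_columns)) {
    keep <- setdiff(seq_len(lens[1]), exclude_columns)
    if (length(keep) == 0L) stop("exclude_columns removes the whole alignment")
    seqs <- vapply(strsplit(seqs, ""), function(s)
      paste(s[keep], collapse = ""), character(1))
  }
  if (any(grepl("[RYSWKMBDHVN?]", seqs)))
    warning(sprintf("marker '%s': sequences contain ambiguity codes; collapsed by exact match only",
                    marker))

  # per-individual multiplicity checks
  copies <- table(records$individual_id)
  if (any(copies > ploidy)) {
    bad <- names(copies)[copies > ploidy][1]
    stop(sprintf("individual '%s' has %d sequences for marker '%s' (ploidy %d)",
                 bad, copies[[bad]], marker, ploidy))
  }
  if (ploidy == 2L && any(copies == 1L)) {
    singles <- names(copies)[copies == 1L]
    message(sprintf("marker '%s': %d individual(s) with a single sequence treated as assumed homozygote: %s",
                    marker, length(singles),
                    paste(utils::head(singles, 10), collapse = ", ")))
    extra <- records[match(singles, records$individual_id), , drop = FALSE]
    extra$seq_id <- paste0(extra$seq_id, "*dup")
    records <- rbind(records, extra)
    records <- records[order(records$seq_id), , drop = FALSE]
    seqs <- toupper(records$sequence)
    if (!is.null(exclude_columns)) {
      keep <- setdiff(seq_len(nchar(seqs[1])), exclude_columns)
      seqs <- vapply(strsplit(seqs, ""), function(s)
        paste(s[keep], collapse = ""), character(1))
    }
  }

  uniq <- unique(seqs)
  hap_of <- match(seqs, uniq)
  hap_ids <- paste0("h", seq_along(uniq))
  members <- lapply(seq_along(uniq), function(i)
    records$individual_id[hap_of == i])
  tab <- .new_haplotype_table(marker, hap_ids, uniq, members)
  tab$count <- vapply(seq_along(uniq), function(i) sum(hap_of == i), integer(1))

  genotypes <- lapply(split(hap_ids[hap_of], records$individual_id), sort)
  universe <- sort(unique(records$individual_id))
  ds <- .new_marker_dataset(marker, ploidy, genotypes, universe)
  list(table = tab, dataset = ds)
}

#' Read a phased-allele FASTA alignment
#'
#' Individual ids are derived from the first whitespace-delimited word of
#' each FASTA header via `id_rule`, a regex with one capture group; the
#' default strips one trailing allele token (`_a`, `_b`, `_1`, `_2`,
#' `/1`, `/2`). Headers that do not match are used verbatim as the
#' individual id.
#'
#' @param path FASTA file, aligned (all sequences equal length).
#' @param marker marker name.
#' @param ploidy 1 or 2.
#' @param id_rule regex with exactly one capture group extracting the
#'   individual id from the sequence name.
#' @param exclude_columns passed to [collapse_haplotypes()].
#' @return list with `table` and `dataset`, as [collapse_haplotypes()].
#' @export
read_phased_fasta <- function(path, marker, ploidy = 2L,
                              id_rule = "^(.*)(?:_[ab12]|/[12])$",
                              exclude_columns = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dna <- tryCatch(ape::read.FASTA(path, type = "DNA"),
                  error = function(e) stop(sprintf(
                    "'%s' is not readable as FASTA: %s", path, conditionMessage(e)),
                    call. = FALSE))
  if (length(dna) == 0L) stop(sprintf("'%s' contains no FASTA records", path))
  seq_id <- vapply(strsplit(names(dna), "[ \t]"), `[`, character(1), 1L)
  sequence <- toupper(vapply(as.character(dna), paste, character(1), collapse = ""))
  ind <- ifelse(grepl(id_rule, seq_id), sub(id_rule, "\\1", seq_id), seq_id)
  records <- data.frame(seq_id = seq_id, individual_id = ind,
                        marker = marker, sequence = sequence,
                        stringsAsFactors = FALSE)
  collapse_haplotypes(records, ploidy = ploidy, exclude_columns = exclude_columns)
}

#' Read a genotype table (TSV)
#'
#' Expected columns: `individual`, `marker`, `allele_1`, `allele_2`.
#' Allele cells may hold aligned sequences (over A, C, G, T, U, N, gap
#' and IUPAC codes) or pre-assigned haplotype labels; a marker is treated
#' as sequence-typed only when every allele cell parses as a sequence.
#' Haploid markers leave `allele_2` empty; an empty `allele_2` on a
#' diploid marker is parsed as an assumed homozygote with a message.
#'
#' @param path TSV file path.
#' @return named list, one element per marker in file order, each a list
#'   with `table` and `dataset`; all datasets share one universe.
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  need <- c("individual", "marker", "allele_1", "allele_2")
  if (!identical(sort(names(df)), sort(need)))
    stop(sprintf("genotype table must have columns %s; found %s",
                 paste(need, collapse = ", "), paste(names(df), collapse = ", ")))
  if (nrow(df) == 0L) stop("genotype table is empty")
  dup <- duplicated(df[, c("individual", "marker")])
  if (any(dup))
    stop(sprintf("duplicate (individual, marker) row: (%s, %s)",
                 df$individual[dup][1], df$marker[dup][1]))
  markers <- unique(df$marker)
  universe <- sort(unique(df$individual))
  out <- list()
  for (m in markers) {
    sub <- df[df$marker == m, , drop = FALSE]
    absent <- setdiff(universe, sub$individual)
    if (length(absent) > 0L)
      stop(sprintf("marker '%s' is missing individuals present for other markers: %s",
                   m, paste(absent, collapse = ", ")))
    haploid <- all(sub$allele_2 == "")
    is_seq <- all(grepl(sprintf("^[%s]+$", DNA_CHARS),
                        toupper(sub$allele_1)))
    if (haploid) {
      a1 <- sub$allele_1
      records <- data.frame(seq_id = sub$individual,
                            individual_id = sub$individual,
                            marker = m, sequence = a1,
                            stringsAsFactors = FALSE)
      out[[m]] <- if (is_seq) collapse_haplotypes(records, ploidy = 1L)
      else .label_dataset(sub$individual, a1, NULL, m, 1L)
    } else {
      miss2 <- sub$allele_2 == ""
      if (any(miss2)) {
        message(sprintf("marker '%s': %d row(s) missing allele_2 parsed as assumed homozygote",
                        m, sum(miss2)))
        sub$allele_2[miss2] <- sub$allele_1[miss2]
      }
      is_seq <- is_seq && all(grepl(sprintf("^[%s]+$", DNA_CHARS),
                                    toupper(sub$allele_2)))
      if (is_seq) {
        records <- data.frame(
          seq_id = c(paste0(sub$individual, "_a"), paste0(sub$individual, "_b")),
          individual_id = rep(sub$individual, 2L),
          marker = m,
          sequence = c(sub$allele_1, sub$allele_2),
          stringsAsFactors = FALSE)
        out[[m]] <- collapse_haplotypes(records, ploidy = 2L)
      } else {
        out[[m]] <- .label_dataset(sub$individual, sub$allele_1, sub$allele_2,
                                   m, 2L)
      }
    }
  }
  out
}

# datasets whose alleles are opaque labels rather than sequences: the
# haplotype table carries NA sequences (no network can be built, but all
# co-occurrence / FFR analyses work)
.label_dataset <- function(ind, a1, a2, marker, ploidy) {
  alleles <- if (ploidy == 2L) c(a1, a2) else a1
  hap_ids <- unique(alleles)
  genotypes <- if (ploidy == 2L)
    lapply(seq_along(ind), function(i) sort(c(a1[i], a2[i])))
  else lapply(seq_along(ind), function(i) a1[i])
  names(genotypes) <- ind
  members <- lapply(hap_ids, function(h) {
    keep <- vapply(genotypes, function(g) h %in% g, logical(1))
    rep(names(genotypes)[keep],
        vapply(genotypes[keep], function(g) sum(g == h), integer(1)))
  })
  tab <- .new_haplotype_table(marker, hap_ids, rep(NA_character_, length(hap_ids)),
                              members)
  tab$count <- vapply(hap_ids, function(h)
    sum(vapply(genotypes, function(g) sum(g == h), integer(1))), integer(1))
  universe <- sort(unique(ind))
  list(table = tab,
       dataset = .new_marker_dataset(marker, ploidy, genotypes, universe))
}

#' Write a haplotype table as TSV
#'
#' Columns: `hap_id`, `marker`, `count`, `members` (comma-separated
#' distinct individuals), `sequence`.
#' @param table a `haplotype_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_tsv <- function(table, path) {
  out <- data.frame(hap_id = table$hap_id, marker = attr(table, "marker"),
                    count = table$count,
                    members = vapply(table$members, function(m)
                      paste(sort(unique(m)), collapse = ","), character(1)),
                    sequence = table$sequence, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write marker datasets as a genotype TSV
#'
#' Inverse of [read_genotype_table()]: writes allele sequences when the
#' haplotype table has them, otherwise the haplotype labels.
#'
#' @param datasets list of `list(table, dataset)` pairs (one per marker).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(datasets, path) {
  rows <- list()
  for (d in datasets) {
    ds <- d$dataset; tab <- d$table
    seq_of <- stats::setNames(tab$sequence, tab$hap_id)
    use_seq <- !anyNA(tab$sequence)
    for (ind in ds$universe) {
      g <- ds$genotypes[[ind]]
      cell <- function(h) if (use_seq) seq_of[[h]] else h
      rows[[length(rows) + 1L]] <- data.frame(
        individual = ind, marker = ds$marker,
        allele_1 = cell(g[1]),
        allele_2 = if (ds$ploidy == 2L) cell(g[2]) else "",
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write phased alleles as aligned FASTA
#'
#' Two records per diploid individual (`id_a`, `id_b`), one per haploid
#' individual; requires sequence-typed haplotypes.
#' @param d a `list(table, dataset)` pair for one marker.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_fasta <- function(d, path) {
  tab <- d$table; ds <- d$dataset
  if (anyNA(tab$sequence))
    stop("dataset has label-only haplotypes; cannot write sequences")
  seq_of <- stats::setNames(tab$sequence, tab$hap_id)
  ids <- character(0); seqs <- character(0)
  for (ind in ds$universe) {
    g <- ds$genotypes[[ind]]
    if (ds$ploidy == 2L) {
      ids <- c(ids, paste0(ind, "_a"), paste0(ind, "_b"))
      seqs <- c(seqs, seq_of[[g[1]]], seq_of[[g[2]]])
    } else {
      ids <- c(ids, ind)
      seqs <- c(seqs, seq_of[[g[1]]])
    }
  }
  writeLines(paste0(">", ids, "\n", seqs), path)
  invisible(path)
}
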