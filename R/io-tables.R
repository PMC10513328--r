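# CSV readers/writers for genotype panels, probe definitions and
# morphological descriptor tables, plus a BED exporter for SNP loci.
#
# A genotype matrix is represented throughout the package as a tibble whose
# first column is `accession` and whose remaining columns are loci, one
# single-character IUPAC call per cell (homozygote A/C/G/T, heterozygote
# ambiguity letter, missing N).

#' Accessors for genotype tibbles
#'
#' `geno_calls()` returns the calls as a character matrix (accessions x
#' loci, accession ids as rownames); `geno_loci()` the ordered locus ids.
#'
#' @param panel A genotype tibble (first column `accession`).
#' @return A character matrix, or a character vector of locus ids.
#' @export
geno_calls <- function(panel) {
  stopifnot(is.data.frame(panel), names(panel)[1] == "accession")
  m <- as.matrix(panel[, -1, drop = FALSE])
  rownames(m) <- panel$accession
  m
}

#' @rdname geno_calls
#' @export
geno_loci <- function(panel) names(panel)[-1]

# Wrap a character matrix back into the tibble convention.
geno_tibble <- function(calls, accessions = rownames(calls)) {
  out <- as_tibble(calls)
  dplyr::bind_cols(tibble(accession = accessions), out)
}

validate_genotype_panel <- function(panel, where = "genotype table") {
  if (names(panel)[1] != "accession") {
    abort(sprintf("%s: first column must be the accession id", where))
  }
  if (anyDuplicated(panel$accession)) {
    abort(sprintf(
      "%s: duplicate accession id '%s'", where,
      panel$accession[duplicated(panel$accession)][1]
    ))
  }
  loci <- geno_loci(panel)
  if (anyDuplicated(loci)) {
    abort(sprintf(
      "%s: duplicate locus id '%s'", where, loci[duplicated(loci)][1]
    ))
  }
  m <- geno_calls(panel)
  bad <- !(m %in% IUPAC_LETTERS) | nchar(m) != 1
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "%s: illegal call '%s' for accession '%s' at locus '%s'",
      where, m[idx[1], idx[2]], rownames(m)[idx[1]], colnames(m)[idx[2]]
    ))
  }
  invisible(panel)
}

#' Read a genotype panel from CSV
#'
#' The expected layout mirrors published chip-genotype supplements: a header
#' row of locus ids, a first column of accession ids, and one IUPAC
#' character per cell (homozygote = A/C/G/T, heterozygote = two-allele
#' ambiguity letter such as R for A/G, missing = N). Lowercase calls are
#' uppercased; invariants (unique ids, rectangular, legal alphabet) are
#' enforced.
#'
#' @param path Path to a CSV file.
#' @return A genotype tibble (first column `accession`, then one column per
#'   locus).
#' @export
read_genotype_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "malformed genotype table '%s': row %d (%s)",
      path, probs$row[1], probs$expected[1]
    ))
  }
  ragged <- which(!stats::complete.cases(raw))
  if (length(ragged) > 0) {
    abort(sprintf(
      "ragged or incomplete row %d in genotype table '%s'",
      ragged[1] + 1L, path
    ))
  }
  names(raw)[1] <- "accession"
  raw <- dplyr::mutate(raw, dplyr::across(-"accession", toupper))
  validate_genotype_panel(raw, where = sprintf("'%s'", path))
  raw
}

#' Write a genotype panel to CSV
#'
#' @param panel A genotype tibble as returned by [read_genotype_table()].
#' @param path Output path.
#' @return `path`, invisibly. Round-trips with [read_genotype_table()].
#' @export
write_genotype_table <- function(panel, path) {
  validate_genotype_panel(panel)
  readr::write_csv(panel, path, progress = FALSE)
  invisible(path)
}

#' Read chip probe definitions from CSV
#'
#' Canonical probe input: one row per array probe with its flanking
#' sequence, the 0-based offset of the SNP within that sequence and the two
#' expected alleles (chip orientation). Optional `chrom_hint`/`pos_hint`
#' columns carry the source-map position used for clustering loci that fail
#' to place.
#'
#' @param path CSV with columns `probe_id`, `sequence`, `snp_offset`,
#'   `allele_a`, `allele_b` and optionally `chrom_hint`, `pos_hint`.
#' @return A probe tibble.
#' @export
read_probe_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("probe_id", "sequence", "snp_offset", "allele_a", "allele_b")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "probe table '%s' lacks column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  probes <- tibble(
    probe_id = raw$probe_id,
    sequence = toupper(raw$sequence),
    snp_offset = as.integer(raw$snp_offset),
    allele_a = toupper(raw$allele_a),
    allele_b = toupper(raw$allele_b),
    chrom_hint = if ("chrom_hint" %in% names(raw)) raw$chrom_hint else NA_character_,
    pos_hint = if ("pos_hint" %in% names(raw)) as.numeric(raw$pos_hint) else NA_real_
  )
  validate_probes(probes)
  probes
}

validate_probes <- function(probes) {
  stopifnot(is.data.frame(probes))
  if (anyDuplicated(probes$probe_id)) {
    abort(sprintf(
      "duplicate probe id '%s'",
      probes$probe_id[duplicated(probes$probe_id)][1]
    ))
  }
  check_iupac(probes$sequence, what = probes$probe_id)
  len <- nchar(probes$sequence)
  bad <- probes$snp_offset < 0 | probes$snp_offset >= len
  if (any(bad)) {
    abort(sprintf(
      "probe '%s': snp_offset %d outside sequence of length %d",
      probes$probe_id[bad][1], probes$snp_offset[bad][1], len[bad][1]
    ))
  }
  bad <- !(probes$allele_a %in% HOM_LETTERS) |
    !(probes$allele_b %in% HOM_LETTERS) |
    probes$allele_a == probes$allele_b
  if (any(bad)) {
    abort(sprintf(
      "probe '%s': alleles must be two distinct bases in A,C,G,T",
      probes$probe_id[bad][1]
    ))
  }
  invisible(probes)
}

#' Read probe sequences from FASTA plus a sidecar CSV
#'
#' Alternative probe input: sequences in FASTA, with a sidecar CSV mapping
#' `probe_id` to `snp_offset`, `allele_a`, `allele_b` (and optional hints).
#'
#' @param fasta_path FASTA of probe sequences (ids must match the sidecar).
#' @param sidecar_path CSV with `probe_id`, `snp_offset`, `allele_a`,
#'   `allele_b` and optional `chrom_hint`, `pos_hint`.
#' @return A probe tibble as from [read_probe_table()].
#' @export
read_probe_fasta <- function(fasta_path, sidecar_path) {
  seqs <- read_fasta(fasta_path)
  side <- readr::read_csv(sidecar_path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (!all(c("probe_id", "snp_offset", "allele_a", "allele_b") %in% names(side))) {
    abort("probe sidecar must provide probe_id, snp_offset, allele_a, allele_b")
  }
  missing_ids <- setdiff(seqs$id, side$probe_id)
  if (length(missing_ids) > 0) {
    abort(sprintf("no sidecar row for probe '%s'", missing_ids[1]))
  }
  merged <- dplyr::inner_join(
    dplyr::rename(seqs, probe_id = "id"), side, by = "probe_id"
  )
  probes <- tibble(
    probe_id = merged$probe_id,
    sequence = merged$sequence,
    snp_offset = as.integer(merged$snp_offset),
    allele_a = toupper(merged$allele_a),
    allele_b = toupper(merged$allele_b),
    chrom_hint = if ("chrom_hint" %in% names(merged)) merged$chrom_hint else NA_character_,
    pos_hint = if ("pos_hint" %in% names(merged)) as.numeric(merged$pos_hint) else NA_real_
  )
  validate_probes(probes)
  probes
}

#' Read a morphological descriptor table from CSV
#'
#' Accession-by-descriptor numeric scores (e.g. CPVO/UPOV ordinal codes).
#' Cells must be complete; impute upstream if needed.
#'
#' @param path CSV with a first column of accession ids and numeric
#'   descriptor columns.
#' @return A tibble, first column `accession`, descriptor columns numeric.
#' @export
read_descriptor_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(raw)[1] <- "accession"
  out <- dplyr::mutate(raw, dplyr::across(-"accession", as.numeric))
  validate_descriptors(out)
  out
}

validate_descriptors <- function(table) {
  stopifnot(is.data.frame(table), names(table)[1] == "accession")
  if (nrow(table) < 3) abort("descriptor table needs at least 3 accessions")
  if (ncol(table) < 3) abort("descriptor table needs at least 2 descriptors")
  vals <- as.matrix(table[, -1, drop = FALSE])
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "missing descriptor value: accession '%s', descriptor '%s'",
      table$accession[idx[1]], colnames(vals)[idx[2]]
    ))
  }
  invisible(table)
}

#' Export SNP loci as BED
#'
#' Writes one BED line per locus (0-based half-open single-base interval),
#' the interchange convention of `bedtools getfasta`-style extraction.
#'
#' @param loci A tibble with columns `target_id`, `snp_pos` (0-based),
#'   `probe_id` and `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  stopifnot(all(c("target_id", "snp_pos", "probe_id", "strand") %in% names(loci)))
  bed <- tibble(
    chrom = loci$target_id,
    start = as.integer(loci$snp_pos),
    end = as.integer(loci$snp_pos) + 1L,
    name = loci$probe_id,
    score = 0L,
    strand = loci$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
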