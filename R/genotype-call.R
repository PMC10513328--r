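# Genotype extraction at projected SNP positions, pseudomolecule
# construction, and merging of the query accession into the reference
# panel. Calls are always expressed in probe (chip) orientation so that
# sequence-derived genotypes and chip genotypes are directly comparable.

#' Extract chip-orientation genotype calls at SNP loci
#'
#' Reads the consensus-genome base at each projected SNP position,
#' complements it when the probe placed on the minus strand, and validates
#' it against the probe's A/B alleles. A genome N gives `missing_base`; a
#' base that is neither allele nor their heterozygote ambiguity letter is an
#' `allele_mismatch`, reported as N under the default policy (a consensus
#' base disagreeing with both chip alleles is more plausibly a placement or
#' consensus artifact than a third allele).
#'
#' @param loci SNP locus tibble from [project_snp()].
#' @param genome Sequence tibble from [read_fasta()].
#' @param probes Probe tibble supplying alleles per `probe_id`.
#' @param keep_mismatch Keep the verbatim (complemented) base for
#'   allele-mismatch loci instead of masking to N (default FALSE).
#' @return Call tibble: `probe_id`, `target_id`, `snp_pos`, `strand`,
#'   `call` (chip orientation), `status` in
#'   called/missing_base/allele_mismatch.
#' @export
extract_call <- function(loci, genome, probes, keep_mismatch = FALSE) {
  stopifnot(is.data.frame(loci), nrow(loci) > 0)
  seqs <- setNames(genome$sequence, genome$id)
  missing_target <- setdiff(loci$target_id, genome$id)
  if (length(missing_target) > 0) {
    abort(sprintf("locus target '%s' not in genome", missing_target[1]))
  }
  out_of_bounds <- loci$snp_pos < 0 |
    loci$snp_pos >= nchar(seqs[loci$target_id])
  if (any(out_of_bounds)) {
    abort(sprintf(
      "snp_pos %d of probe '%s' outside sequence '%s'",
      loci$snp_pos[out_of_bounds][1], loci$probe_id[out_of_bounds][1],
      loci$target_id[out_of_bounds][1]
    ))
  }
  base <- substr(seqs[loci$target_id], loci$snp_pos + 1L, loci$snp_pos + 1L)
  minus <- loci$strand == "-"
  base[minus] <- complement_base(base[minus])

  pr <- dplyr::select(probes, "probe_id", "allele_a", "allele_b")
  j <- dplyr::left_join(dplyr::mutate(loci, .base = unname(base)), pr,
                        by = "probe_id")
  if (anyNA(j$allele_a)) {
    abort(sprintf(
      "no probe record for locus '%s'", j$probe_id[is.na(j$allele_a)][1]
    ))
  }
  het <- iupac_het(j$allele_a, j$allele_b)
  ok <- j$.base == j$allele_a | j$.base == j$allele_b | j$.base == het
  status <- ifelse(ok, "called",
                   ifelse(j$.base == "N", "missing_base", "allele_mismatch"))
  call <- j$.base
  call[status == "missing_base"] <- "N"
  if (!keep_mismatch) call[status == "allele_mismatch"] <- "N"
  tibble(
    probe_id = j$probe_id, target_id = j$target_id, snp_pos = j$snp_pos,
    strand = j$strand, call = call, status = status
  )
}

#' Concatenate genotype calls into a pseudomolecule
#'
#' Places one character per panel locus, in the panel's canonical locus
#' order, into a continuous nucleotide string; loci without a call become
#' N. Equal-length pseudomolecules across accessions are positionally
#' aligned by construction, so chip genotypes and sequence-derived
#' genotypes can be compared as sequences.
#'
#' @param calls Call tibble from [extract_call()] (or any tibble with
#'   `probe_id` and `call`). Calls for loci outside `panel_loci` are an
#'   error, as are duplicate calls for one locus.
#' @param panel_loci Ordered character vector of panel locus ids.
#' @param accession_id Id for the resulting sequence record.
#' @return A one-row sequence tibble (`id`, `sequence`) serializable with
#'   [write_fasta()].
#' @export
build_pseudomolecule <- function(calls, panel_loci, accession_id) {
  stopifnot(length(panel_loci) > 0, !anyDuplicated(panel_loci))
  if (anyDuplicated(calls$probe_id)) {
    abort(sprintf(
      "duplicate call for locus '%s'",
      calls$probe_id[duplicated(calls$probe_id)][1]
    ))
  }
  outside <- setdiff(calls$probe_id, panel_loci)
  if (length(outside) > 0) {
    abort(sprintf("call for locus '%s' not in the panel", outside[1]))
  }
  chars <- rep("N", length(panel_loci))
  chars[match(calls$probe_id, panel_loci)] <- calls$call
  tibble(id = accession_id, sequence = paste(chars, collapse = ""))
}

#' Called/uncalled locus summary
#'
#' The headline reporter of the genotyping stage: how many panel loci
#' received a genotype call. Percentages are rounded half-up to two
#' decimals and reconciled so they sum to exactly 100.00 (the uncalled
#' percentage is computed as 100 minus the called percentage).
#'
#' @param total_loci Total panel loci (> 0).
#' @param uncalled Number of loci without a call (between 0 and
#'   `total_loci`).
#' @return One-row tibble: `called_count`, `called_pct`, `uncalled_pct`.
#' @export
#' @examples
#' call_summary(3541, 32) # 3509 called, 99.10% / 0.90%
call_summary <- function(total_loci, uncalled) {
  stopifnot(length(total_loci) == 1, length(uncalled) == 1)
  if (total_loci <= 0) abort("total_loci must be positive")
  if (uncalled < 0 || uncalled > total_loci) {
    abort("uncalled must be between 0 and total_loci")
  }
  called <- total_loci - uncalled
  called_pct <- round_half_up(100 * called / total_loci, 2)
  tibble(
    called_count = as.integer(called),
    called_pct = called_pct,
    uncalled_pct = round_half_up(100 - called_pct, 2)
  )
}

#' Append a pseudomolecule to a genotype panel
#'
#' Splits the pseudomolecule back into per-locus calls and appends the
#' accession as the last row of the panel; existing rows are untouched.
#'
#' @param panel Genotype tibble (first column `accession`).
#' @param pseudo One-row sequence tibble from [build_pseudomolecule()];
#'   its length must equal the panel locus count and its id must be new.
#' @return The extended genotype tibble.
#' @export
merge_into_panel <- function(panel, pseudo) {
  validate_genotype_panel(panel)
  stopifnot(is.data.frame(pseudo), nrow(pseudo) == 1)
  loci <- geno_loci(panel)
  if (nchar(pseudo$sequence) != length(loci)) {
    abort(sprintf(
      "pseudomolecule length %d != panel locus count %d",
      nchar(pseudo$sequence), length(loci)
    ))
  }
  if (pseudo$id %in% panel$accession) {
    abort(sprintf("accession '%s' already in the panel", pseudo$id))
  }
  chars <- strsplit(pseudo$sequence, "", fixed = TRUE)[[1]]
  row <- geno_tibble(matrix(chars, nrow = 1, dimnames = list(NULL, loci)),
                     accessions = pseudo$id)
  out <- dplyr::bind_rows(panel, row)
  validate_genotype_panel(out)
  out
}
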