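# LD pruning on minor-allele dosages: squared Pearson correlation over
# pairwise-complete entries, applied in a sliding window so that retained
# markers are approximately independent.

#' Minor-allele dosage matrix of a genotype panel
#'
#' Encodes each call as the count of the locus's minor allele (0, 1 or 2);
#' missing calls and genotypes carrying an allele other than the locus's
#' two most frequent become NA.
#'
#' @param panel Genotype tibble.
#' @param stats Marker statistics from [marker_stats()] (recomputed when
#'   NULL); only loci present in `stats` are encoded.
#' @return Numeric accession-by-locus matrix of dosages.
#' @export
geno_dosage <- function(panel, stats = NULL) {
  if (is.null(stats)) stats <- marker_stats(panel)
  m <- geno_calls(panel)[, stats$locus_id, drop = FALSE]
  out <- matrix(NA_real_, nrow(m), ncol(m),
                dimnames = dimnames(m))
  for (l in seq_len(ncol(m))) {
    calls <- m[, l]
    keep <- calls %in% DIPLOID_CODES
    if (!any(keep)) next
    is_het <- calls %in% HET_LETTERS
    counts <- c(A = 0, C = 0, G = 0, T = 0)
    tab_het <- table(unlist(iupac_alleles(calls[keep & is_het])))
    tab_hom <- table(calls[keep & !is_het])
    counts[names(tab_het)] <- counts[names(tab_het)] + as.integer(tab_het)
    counts[names(tab_hom)] <- counts[names(tab_hom)] +
      2L * as.integer(tab_hom)
    present <- names(counts)[counts > 0]
    ord <- present[order(-counts[present], match(present, names(counts)))]
    major <- ord[1]
    minor <- if (length(ord) >= 2) ord[2] else NA_character_
    dos <- rep(NA_real_, length(calls))
    dos[calls == major] <- 0
    if (!is.na(minor)) {
      dos[calls == minor] <- 2
      dos[calls == iupac_het(major, minor)] <- 1
    }
    out[, l] <- dos
  }
  out
}

#' Squared Pearson correlation of two dosage vectors
#'
#' Computed over pairwise-complete entries. With fewer than two complete
#' pairs, or zero variance in either vector, r2 is undefined and NA is
#' returned; [ld_prune()] treats NA conservatively as r2 = 1.
#'
#' @param dosages_x,dosages_y Numeric vectors of dosages in 0/1/2 with NA
#'   for missing.
#' @return A single numeric r2 in \[0, 1\], or NA.
#' @export
ld_r2 <- function(dosages_x, dosages_y) {
  stopifnot(length(dosages_x) == length(dosages_y))
  ok <- !is.na(dosages_x) & !is.na(dosages_y)
  if (sum(ok) < 2) return(NA_real_)
  x <- dosages_x[ok]
  y <- dosages_y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Sliding-window LD pruning
#'
#' Slides a window of `ld_window` loci by `ld_step` across the panel's
#' locus order (genome order when positions are known upstream, else input
#' order). Within a window, while any retained pair exceeds `ld_r2_max`
#' (undefined r2 counts as exceeding), the pair with the highest r2 is
#' taken (ties: first pair in order) and its lower-MAF member removed
#' (tie: the later locus in order). Fully deterministic.
#'
#' @param panel Genotype tibble.
#' @param stats Marker statistics from [marker_stats()] (recomputed when
#'   NULL); supplies the MAF used for removal decisions.
#' @param config A [qc_config()].
#' @return Character vector of retained locus ids, in panel order.
#' @export
ld_prune <- function(panel, stats = NULL, config = qc_config()) {
  if (is.null(stats)) stats <- marker_stats(panel)
  dos <- geno_dosage(panel, stats)
  loci <- colnames(dos)
  n <- length(loci)
  if (n == 0) return(character(0))
  maf <- setNames(stats$maf, stats$locus_id)[loci]
  retained <- rep(TRUE, n)
  w <- config$ld_window
  for (s in seq(1, n, by = config$ld_step)) {
    win <- s:min(s + w - 1, n)
    # r2 of every pair in the window, computed once; undefined r2 (zero
    # variance or <2 complete pairs) is conservatively 1
    R2 <- suppressWarnings(
      cor(dos[, win, drop = FALSE], use = "pairwise.complete.obs")
    )^2
    R2[is.na(R2)] <- 1
    diag(R2) <- 0
    repeat {
      active <- which(retained[win])
      if (length(active) < 2) break
      M <- R2[active, active, drop = FALSE]
      M[lower.tri(M, diag = TRUE)] <- -1
      m <- max(M)
      if (m <= config$ld_r2_max) break
      cand <- which(M == m, arr.ind = TRUE)
      cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
      pair <- win[active[c(cand[1, 1], cand[1, 2])]]
      drop <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
              else if (maf[pair[2]] < maf[pair[1]]) pair[2]
              else max(pair)
      retained[drop] <- FALSE
    }
    if (max(win) == n) break
  }
  loci[retained]
}
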