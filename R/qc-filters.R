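# Panel QC for duplicate detection: per-genotype missingness filter,
# per-marker heterozygosity and Hardy-Weinberg filters. Thresholds default
# to the values commonly used for germplasm duplicate screens (missingness
# 10%, marker heterozygosity 0.1, HWE alpha 0.05, LD r2 0.8, homozygous
# difference 0.1%).

#' QC configuration for the duplicate-detection pipeline
#'
#' @param max_genotype_missing Maximum fraction of missing calls per
#'   accession (default 0.10).
#' @param max_marker_het Maximum heterozygote fraction per marker
#'   (default 0.10).
#' @param hwe_alpha Markers with Hardy-Weinberg chi-square p below this are
#'   removed (default 0.05; no multiple-testing correction).
#' @param ld_r2_max Markers are pruned until no retained pair within a
#'   window exceeds this squared correlation (default 0.8).
#' @param ld_window,ld_step Sliding-window size and step in loci
#'   (defaults 50 and 5).
#' @param dup_homdiff_max Strict upper bound on the homozygous difference
#'   for a duplicate pair (default 0.001; a pair at exactly 0.001 is not a
#'   duplicate).
#' @param het_scope Apply the heterozygosity threshold per `"genotype"`
#'   (default: accessions above the threshold removed) or per `"marker"`
#'   (markers above it removed). The per-genotype default is chosen
#'   because duplicate screens run on small genotype sets, where a
#'   per-marker threshold below 1/n would discard every marker carrying a
#'   heterozygote; see the methods vignette.
#' @param filter_order `"het_hwe_then_ld"` (default) or
#'   `"ld_then_het_hwe"`: order of the two marker-filter stages.
#' @return A validated list of class `qc_config`.
#' @export
qc_config <- function(max_genotype_missing = 0.10,
                      max_marker_het = 0.10,
                      hwe_alpha = 0.05,
                      ld_r2_max = 0.8,
                      ld_window = 50,
                      ld_step = 5,
                      dup_homdiff_max = 0.001,
                      het_scope = c("genotype", "marker"),
                      filter_order = c("het_hwe_then_ld",
                                       "ld_then_het_hwe")) {
  het_scope <- match.arg(het_scope)
  filter_order <- match.arg(filter_order)
  fracs <- c(max_genotype_missing, max_marker_het, hwe_alpha, ld_r2_max,
             dup_homdiff_max)
  if (any(fracs < 0 | fracs > 1)) {
    abort("all qc_config fractions must lie in [0, 1]")
  }
  if (ld_step < 1 || ld_window < ld_step) {
    abort("qc_config requires ld_window >= ld_step >= 1")
  }
  structure(
    list(max_genotype_missing = max_genotype_missing,
         max_marker_het = max_marker_het,
         hwe_alpha = hwe_alpha,
         ld_r2_max = ld_r2_max,
         ld_window = as.integer(ld_window),
         ld_step = as.integer(ld_step),
         dup_homdiff_max = dup_homdiff_max,
         het_scope = het_scope,
         filter_order = filter_order),
    class = "qc_config"
  )
}

#' Filter accessions by missing-call fraction
#'
#' @param panel Genotype tibble.
#' @param config A [qc_config()].
#' @return List with `retained` (the filtered genotype tibble) and
#'   `removed` (character vector of dropped accession ids). An accession
#'   is kept iff its fraction of N calls is at most
#'   `max_genotype_missing`.
#' @export
filter_genotypes_by_missingness <- function(panel, config = qc_config()) {
  m <- geno_calls(panel)
  frac_missing <- rowMeans(m == "N")
  keep <- frac_missing <= config$max_genotype_missing
  list(
    retained = panel[keep, , drop = FALSE],
    removed = panel$accession[!keep]
  )
}

#' Per-marker call, heterozygosity, allele-frequency and HWE statistics
#'
#' For each locus, over non-missing calls: the heterozygote fraction,
#' allele counts from dosages (homozygote = 2 copies, heterozygote = 1 of
#' each), the minor-allele frequency, and a Hardy-Weinberg chi-square test
#' on the genotype classes of the two most frequent alleles (genotypes
#' carrying a third allele are excluded from the HWE classes). Loci with
#' no non-missing call are dropped with a warning.
#'
#' @param panel Genotype tibble.
#' @return Tibble with one row per retained locus: `locus_id`, `n_called`,
#'   `het_fraction`, `maf`, `hwe_chi2`, `hwe_p`.
#' @export
marker_stats <- function(panel) {
  m <- geno_calls(panel)
  loci <- colnames(m)
  n_loci <- ncol(m)
  out <- vector("list", n_loci)
  dropped <- character(0)
  for (l in seq_len(n_loci)) {
    calls <- m[, l]
    calls <- calls[calls %in% DIPLOID_CODES]
    n_called <- length(calls)
    if (n_called == 0) {
      dropped <- c(dropped, loci[l])
      next
    }
    is_het <- calls %in% HET_LETTERS
    counts <- c(A = 0, C = 0, G = 0, T = 0)
    tab_het <- table(unlist(iupac_alleles(calls[is_het])))
    tab_hom <- table(calls[!is_het])
    counts[names(tab_het)] <- counts[names(tab_het)] + as.integer(tab_het)
    counts[names(tab_hom)] <- counts[names(tab_hom)] +
      2L * as.integer(tab_hom)
    total <- sum(counts)
    major <- names(counts)[which.max(counts)]
    present <- names(counts)[counts > 0]
    minor <- if (length(present) >= 2) {
      ord <- present[order(-counts[present], match(present, names(counts)))]
      ord[2]
    } else {
      NA_character_
    }
    minor_count <- if (is.na(minor)) 0 else counts[[minor]]
    if (is.na(minor)) {
      hwe <- list(chi2 = 0, p = 1)
    } else {
      het_code <- iupac_het(major, minor)
      hwe <- hwe_chisq(sum(calls == major), sum(calls == het_code),
                       sum(calls == minor))
    }
    out[[l]] <- tibble(
      locus_id = loci[l],
      n_called = n_called,
      het_fraction = mean(is_het),
      maf = minor_count / total,
      hwe_chi2 = hwe$chi2,
      hwe_p = hwe$p
    )
  }
  if (length(dropped) > 0) {
    warn(sprintf(
      "marker_stats: %d locus/loci with no non-missing call removed (first: '%s')",
      length(dropped), dropped[1]
    ))
  }
  dplyr::bind_rows(out)
}

hwe_chisq <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p_hat <- (2 * n_AA + n_Aa) / (2 * n)
  if (p_hat == 0 || p_hat == 1) return(list(chi2 = 0, p = 1))
  expected <- c(n * p_hat^2, 2 * n * p_hat * (1 - p_hat),
                n * (1 - p_hat)^2)
  observed <- c(n_AA, n_Aa, n_aa)
  use <- expected > 0
  chi2 <- sum((observed[use] - expected[use])^2 / expected[use])
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the p^2 / 2pq / q^2 expectation at the observed allele
#' frequency. Monomorphic input gives chi2 = 0, p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (vectors recycle to a common
#'   length; each triple must sum to at least 1).
#' @return Tibble with columns `chi2` and `p`.
#' @export
#' @examples
#' hwe_test(30, 40, 30) # chi2 = 4, p ~ 0.0455
hwe_test <- function(n_AA, n_Aa, n_aa) {
  counts <- vctrs_recycle(n_AA, n_Aa, n_aa)
  if (any(counts$a < 0 | counts$b < 0 | counts$c < 0)) {
    abort("genotype counts must be non-negative")
  }
  if (any(counts$a + counts$b + counts$c < 1)) {
    abort("each genotype-count triple must sum to at least 1")
  }
  res <- purrr::pmap(list(counts$a, counts$b, counts$c), hwe_chisq)
  tibble(
    chi2 = vapply(res, `[[`, numeric(1), "chi2"),
    p = vapply(res, `[[`, numeric(1), "p")
  )
}

vctrs_recycle <- function(a, b, c) {
  n <- max(length(a), length(b), length(c))
  list(a = rep_len(a, n), b = rep_len(b, n), c = rep_len(c, n))
}

#' Apply the heterozygosity and HWE marker filters
#'
#' Removes markers whose heterozygote fraction exceeds
#' `max_marker_het` or whose HWE p-value falls below `hwe_alpha`. Under
#' `het_scope = "genotype"` the heterozygosity threshold is instead
#' applied per accession (accessions above it removed) and only the HWE
#' filter acts on markers.
#'
#' @param panel Genotype tibble.
#' @param stats Marker statistics from [marker_stats()] (recomputed when
#'   NULL).
#' @param config A [qc_config()].
#' @return List with `retained` (filtered panel), `removed_loci` and
#'   `removed_accessions`.
#' @export
filter_markers_het_hwe <- function(panel, stats = NULL,
                                   config = qc_config()) {
  if (is.null(stats)) stats <- marker_stats(panel)
  removed_acc <- character(0)
  if (config$het_scope == "genotype") {
    m <- geno_calls(panel)
    het_frac <- rowMeans(matrix(m %in% HET_LETTERS, nrow = nrow(m)))
    removed_acc <- panel$accession[het_frac > config$max_marker_het]
    panel <- panel[!(panel$accession %in% removed_acc), , drop = FALSE]
    keep_loci <- stats$locus_id[stats$hwe_p >= config$hwe_alpha]
  } else {
    keep_loci <- stats$locus_id[
      stats$het_fraction <= config$max_marker_het &
        stats$hwe_p >= config$hwe_alpha
    ]
  }
  removed_loci <- setdiff(geno_loci(panel), keep_loci)
  list(
    retained = dplyr::select(panel, "accession", dplyr::all_of(keep_loci)),
    removed_loci = removed_loci,
    removed_accessions = removed_acc
  )
}
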