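# Identity-by-state duplicate detection: among loci where both accessions
# are homozygous and non-missing, the fraction of differing calls
# ("homozygous difference"); pairs strictly below the threshold are
# duplicate edges, duplicate groups are the connected components.

#' Homozygous difference between two accessions
#'
#' Over sites where both calls are homozygous (A/C/G/T), the fraction of
#' sites with different calls. With no comparable homozygous site the
#' value is undefined and NA is returned with a warning; such pairs are
#' excluded from duplicate calling.
#'
#' @param calls_x,calls_y Character vectors of IUPAC calls (one accession
#'   row each, equal length).
#' @return A fraction in \[0, 1\], or NA.
#' @export
hom_diff <- function(calls_x, calls_y) {
  stopifnot(length(calls_x) == length(calls_y))
  both_hom <- calls_x %in% HOM_LETTERS & calls_y %in% HOM_LETTERS
  if (!any(both_hom)) {
    warn("hom_diff: no site where both calls are homozygous; returning NA")
    return(NA_real_)
  }
  mean(calls_x[both_hom] != calls_y[both_hom])
}

#' Pairwise homozygous-difference matrix
#'
#' @param panel Genotype tibble.
#' @return Symmetric numeric matrix of homozygous differences (NA where a
#'   pair has no comparable homozygous site; diagonal 0).
#' @export
hom_diff_matrix <- function(panel) {
  m <- geno_calls(panel)
  n <- nrow(m)
  hom <- matrix(m %in% HOM_LETTERS, nrow = n)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  n_na <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- hom[i, ] & hom[j, ]
      if (!any(both)) {
        out[i, j] <- out[j, i] <- NA_real_
        n_na <- n_na + 1L
        next
      }
      out[i, j] <- out[j, i] <- mean(m[i, both] != m[j, both])
    }
  }
  if (n_na > 0) {
    warn(sprintf(
      "hom_diff_matrix: %d pair(s) with no comparable homozygous site excluded from duplicate calling",
      n_na
    ))
  }
  out
}

#' Duplicate detection by homozygous difference
#'
#' Accession pairs whose homozygous difference is strictly below
#' `dup_homdiff_max` are duplicate edges; duplicate groups are the
#' connected components of that graph, each represented by its first
#' member in panel order. Retained genotypes are the representatives
#' (singletons represent themselves).
#'
#' @param panel Genotype tibble (marker filters already applied).
#' @param config A [qc_config()].
#' @return List of class `dup_result`: `homdiff` (pairwise matrix),
#'   `groups` (tibble `accession`, `group`, `representative`),
#'   `representatives`, `retained` (character vectors).
#' @export
find_duplicates <- function(panel, config = qc_config()) {
  acc <- panel$accession
  hd <- hom_diff_matrix(panel)
  edge_idx <- which(upper.tri(hd) & !is.na(hd) & hd < config$dup_homdiff_max,
                    arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(acc), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = acc)
  if (nrow(edge_idx) > 0) {
    g <- igraph::add_edges(g, t(cbind(edge_idx[, 1], edge_idx[, 2])))
  }
  comp <- igraph::components(g)
  membership <- comp$membership
  reps <- vapply(seq_len(comp$no),
                 function(k) acc[membership == k][1], character(1))
  groups <- tibble(
    accession = acc,
    group = as.integer(membership),
    representative = reps[membership]
  )
  structure(
    list(homdiff = hd, groups = groups, representatives = reps,
         retained = reps),
    class = "dup_result"
  )
}

#' Full identity-by-state duplicate-screening pipeline
#'
#' Chains the QC stages in the configured order: accession missingness
#' filter, marker heterozygosity + HWE filters, sliding-window LD pruning,
#' then homozygous-difference duplicate calling on the retained markers
#' (swap the two marker stages with `filter_order = "ld_then_het_hwe"`).
#'
#' @param panel Genotype tibble.
#' @param config A [qc_config()].
#' @return Object of class `qc_report`: list with per-stage retained ids
#'   (`retained_after_missingness`, `retained_after_het_hwe`,
#'   `retained_after_ld`), `marker_stats`, `homdiff`, `duplicate_groups`,
#'   `representatives`, `retained_genotypes` and the `config`. `tidy()`
#'   gives the duplicate groups, `glance()` the stage counts.
#' @export
ibs_dedup <- function(panel, config = qc_config()) {
  stage1 <- filter_genotypes_by_missingness(panel, config)
  p <- stage1$retained
  if (nrow(p) < 2) abort("fewer than 2 accessions survive the missingness filter")
  stats <- marker_stats(p)
  p <- dplyr::select(p, "accession", dplyr::all_of(stats$locus_id))

  apply_het_hwe <- function(p) {
    st <- stats[stats$locus_id %in% geno_loci(p), , drop = FALSE]
    filter_markers_het_hwe(p, st, config)$retained
  }
  apply_ld <- function(p) {
    st <- stats[stats$locus_id %in% geno_loci(p), , drop = FALSE]
    keep <- ld_prune(p, st, config)
    dplyr::select(p, "accession", dplyr::all_of(keep))
  }

  if (config$filter_order == "het_hwe_then_ld") {
    p_het <- apply_het_hwe(p)
    p_ld <- apply_ld(p_het)
    retained_het <- geno_loci(p_het)
    retained_ld <- geno_loci(p_ld)
  } else {
    p_ld0 <- apply_ld(p)
    p_ld <- apply_het_hwe(p_ld0)
    retained_het <- geno_loci(p_ld)
    retained_ld <- geno_loci(p_ld0)
  }

  dup <- find_duplicates(p_ld, config)
  structure(
    list(
      retained_after_missingness = stage1$retained$accession,
      removed_by_missingness = stage1$removed,
      retained_after_het_hwe = retained_het,
      retained_after_ld = retained_ld,
      marker_stats = stats,
      homdiff = dup$homdiff,
      duplicate_groups = dup$groups,
      representatives = dup$representatives,
      retained_genotypes = dup$retained,
      config = config
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  g <- glance(x)
  cat("Identity-by-state duplicate screen\n")
  cat(sprintf("  genotypes after missingness filter: %d\n",
              g$n_genotypes_after_missingness))
  cat(sprintf("  markers after het+HWE filter:       %d\n",
              g$n_markers_after_het_hwe))
  cat(sprintf("  markers after LD pruning:           %d\n",
              g$n_markers_after_ld))
  cat(sprintf("  duplicate groups (size > 1):        %d\n",
              g$n_duplicate_groups))
  cat(sprintf("  genotypes retained after dedup:     %d\n",
              g$n_genotypes_retained))
  invisible(x)
}

#' @describeIn ibs_dedup Duplicate group membership as a tibble.
#' @param x A `qc_report`.
#' @param ... Unused.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) x$duplicate_groups

#' @describeIn ibs_dedup One-row stage-count summary.
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  sizes <- table(x$duplicate_groups$group)
  tibble(
    n_genotypes_after_missingness = length(x$retained_after_missingness),
    n_markers_after_het_hwe = length(x$retained_after_het_hwe),
    n_markers_after_ld = length(x$retained_after_ld),
    n_duplicate_groups = sum(sizes > 1),
    n_genotypes_retained = length(x$retained_genotypes)
  )
}
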