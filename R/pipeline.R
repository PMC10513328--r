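# End-to-end pipeline: probe placement -> SNP projection -> genotype
# extraction -> pseudomolecule -> merge into the reference panel ->
# p-distance + NJ tree with bootstrap, plus the identity-by-state
# duplicate screen on the merged panel. Every intermediate can be written
# beside a JSON summary echoing the effective configuration.

#' Pipeline configuration
#'
#' Collects every stage parameter with its module default; a configuration
#' echo is written beside the outputs by [run_pipeline()].
#'
#' @param k Probe-placement seed length (default 21).
#' @param min_identity Minimum placement identity (default 0.95).
#' @param keep_mismatch Keep verbatim allele-mismatch calls (default
#'   FALSE).
#' @param min_sites Minimum comparable sites per accession pair (default
#'   50).
#' @param replicates Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap resampling (default 1).
#' @param allele_aware Allele-aware distance weights (default FALSE).
#' @param max_gap Gap for clustering uncalled loci, bp (default 1e7).
#' @param accession_id Id of the query accession (default "query").
#' @param qc A [qc_config()] for the duplicate screen.
#' @param pca_scale Standardize descriptors before PCA (default TRUE).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 21, min_identity = 0.95,
                            keep_mismatch = FALSE, min_sites = 50,
                            replicates = 1000, seed = 1,
                            allele_aware = FALSE, max_gap = 1e7,
                            accession_id = "query", qc = qc_config(),
                            pca_scale = TRUE) {
  structure(
    list(k = as.integer(k), min_identity = min_identity,
         keep_mismatch = keep_mismatch, min_sites = as.integer(min_sites),
         replicates = as.integer(replicates), seed = as.integer(seed),
         allele_aware = allele_aware, max_gap = max_gap,
         accession_id = accession_id, qc = qc, pca_scale = pca_scale),
    class = "pipeline_config"
  )
}

#' Run the genome-vs-panel comparison pipeline
#'
#' Chains [place_all()], [project_snp()], [extract_call()],
#' [build_pseudomolecule()], [merge_into_panel()],
#' [p_distance_matrix()], [bootstrap_support()] and [ibs_dedup()] on one
#' query genome against one reference panel, writing every intermediate
#' when `out_dir` is given. Loci that fail to place or call are clustered
#' into genomic regions via the probes' map hints when available.
#'
#' @param genome Query consensus genome, sequence tibble (see
#'   [read_fasta()]).
#' @param probes Probe tibble (see [read_probe_table()]).
#' @param panel Reference genotype tibble (see [read_genotype_table()]);
#'   locus ids must match probe ids.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for intermediates.
#' @return List of class `pipeline_result`: `placements`,
#'   `placement_summary`, `loci`, `calls`, `call_summary`, `pseudo`,
#'   `merged`, `dist`, `tree`, `dedup`, `uncalled_regions`, `config`.
#' @export
run_pipeline <- function(genome, probes, panel,
                         config = pipeline_config(), out_dir = NULL) {
  validate_genotype_panel(panel)
  panel_loci <- geno_loci(panel)
  unknown <- setdiff(panel_loci, probes$probe_id)
  if (length(unknown) > 0) {
    abort(sprintf("panel locus '%s' has no probe definition", unknown[1]))
  }
  probes_used <- probes[probes$probe_id %in% panel_loci, , drop = FALSE]

  placements <- place_all(probes_used, genome, k = config$k,
                          min_identity = config$min_identity)
  psum <- placement_summary(placements)
  unique_pl <- placements[placements$status == "unique", , drop = FALSE]
  loci <- project_snp(unique_pl, probes_used)
  calls <- extract_call(loci, genome, probes_used,
                        keep_mismatch = config$keep_mismatch)
  called <- calls[calls$status == "called" |
                    (config$keep_mismatch &
                       calls$status == "allele_mismatch"), , drop = FALSE]
  csum <- call_summary(length(panel_loci),
                       length(panel_loci) - nrow(called))
  pseudo <- build_pseudomolecule(
    dplyr::select(called, "probe_id", "call"),
    panel_loci, config$accession_id
  )
  merged <- merge_into_panel(panel, pseudo)
  dm <- p_distance_matrix(merged, min_sites = config$min_sites,
                          allele_aware = config$allele_aware)
  tree <- bootstrap_support(merged, replicates = config$replicates,
                            seed = config$seed,
                            min_sites = config$min_sites,
                            allele_aware = config$allele_aware)
  dedup <- ibs_dedup(merged, config$qc)

  uncalled_ids <- setdiff(panel_loci, called$probe_id)
  hints <- probes_used[probes_used$probe_id %in% uncalled_ids &
                         !is.na(probes_used$chrom_hint) &
                         !is.na(probes_used$pos_hint), , drop = FALSE]
  uncalled_regions <- cluster_uncalled(
    tibble(chrom = hints$chrom_hint, pos = hints$pos_hint),
    max_gap = config$max_gap
  )

  result <- structure(
    list(placements = placements, placement_summary = psum, loci = loci,
         calls = calls, call_summary = csum, pseudo = pseudo,
         merged = merged, dist = dm, tree = tree, dedup = dedup,
         uncalled_regions = uncalled_regions, config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# Write every pipeline intermediate plus a JSON summary echoing the
# configuration and per-stage counts. Reports print 1-based positions in
# clearly named columns; BED stays 0-based half-open.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pl <- dplyr::mutate(result$placements,
                      start_0based = .data$start, .keep = "unused")
  readr::write_tsv(
    dplyr::select(pl, "probe_id", "target_id", "start_0based", "end",
                  "strand", "identity", "n_best", "status"),
    file.path(out_dir, "placements.tsv"), progress = FALSE
  )
  readr::write_tsv(
    dplyr::mutate(result$calls, pos_1based = .data$snp_pos + 1L,
                  .keep = "unused"),
    file.path(out_dir, "calls.tsv"), progress = FALSE
  )
  write_bed(result$loci, file.path(out_dir, "snp_loci.bed"))
  write_fasta(result$pseudo, file.path(out_dir, "pseudomolecule.fasta"))
  write_genotype_table(result$merged, file.path(out_dir, "merged_panel.csv"))
  readr::write_tsv(
    as_tibble(as.matrix(result$dist), rownames = "accession"),
    file.path(out_dir, "distances.tsv"), progress = FALSE
  )
  write_newick(result$tree, file.path(out_dir, "tree.nwk"))
  readr::write_tsv(tidy(result$dedup),
                   file.path(out_dir, "duplicate_groups.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$uncalled_regions,
                   file.path(out_dir, "uncalled_regions.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(
      config = unclass_config(result$config),
      placement_summary = result$placement_summary,
      call_summary = result$call_summary,
      dedup = glance(result$dedup)
    ),
    file.path(out_dir, "summary.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$qc <- unclass(out$qc)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Genome-vs-panel comparison pipeline\n")
  cat(sprintf("  probes placed unique/ambiguous/unplaced: %s\n",
              paste(x$placement_summary$n, collapse = "/")))
  cat(sprintf("  loci called: %d (%.2f%%), uncalled %.2f%%\n",
              x$call_summary$called_count, x$call_summary$called_pct,
              x$call_summary$uncalled_pct))
  cat(sprintf("  accessions in merged panel: %d\n", nrow(x$merged)))
  print(x$dedup)
  invisible(x)
}
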