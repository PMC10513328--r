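# Locus-resampling bootstrap for NJ trees: loci are resampled with
# replacement, distances and the NJ tree are recomputed, and each internal
# bipartition of the original tree is scored by the percentage of
# replicates in which it recurs.

# Canonical keys of the non-trivial bipartitions of an unrooted phylo,
# named by the internal node defining each (child side of the edge).
# A split is keyed by the sorted tip set on the side NOT containing the
# reference (first) tip label, so keys are comparable across trees with
# the same leaf set.
tree_splits <- function(tree, ref_tip = NULL) {
  ntip <- length(tree$tip.label)
  if (is.null(ref_tip)) ref_tip <- sort(tree$tip.label)[1]
  edge <- stats::reorder(tree, "postorder")$edge
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]
    ch <- edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  root <- ntip + 1L
  internal <- setdiff(seq_len(ntip + tree$Nnode)[-seq_len(ntip)], root)
  keys <- vapply(internal, function(v) {
    set <- desc[[v]]
    if (length(set) < 2 || length(set) > ntip - 2) return(NA_character_)
    if (ref_tip %in% set) set <- setdiff(tree$tip.label, set)
    paste(sort(set), collapse = "\r")
  }, character(1))
  setNames(keys, internal)
}

#' Neighbor-joining tree with locus-resampling bootstrap supports
#'
#' Builds the NJ tree of the full panel, then resamples loci (columns)
#' with replacement `replicates` times, recomputing distances and the NJ
#' tree each time. The support of each internal bipartition of the
#' original tree is the percentage of replicates whose tree contains it,
#' stored in `node.label`. A replicate in which some accession pair has
#' zero comparable sites is skipped and counted in a warning; supports are
#' then percentages of the evaluable replicates. Fixed seed gives
#' bit-identical supports.
#'
#' @inheritParams p_distance_matrix
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the locus resampling.
#' @return The NJ `phylo` tree of the full panel with bootstrap supports
#'   (percent) as `node.label` (NA for the root).
#' @export
bootstrap_support <- function(panel, replicates = 1000, seed = 1,
                              min_sites = 50, allele_aware = FALSE) {
  stopifnot(replicates >= 1)
  m <- geno_calls(panel)
  if (nrow(m) < 3) abort("bootstrap_support needs at least 3 accessions")
  labels <- rownames(m)
  idx_full <- encode_calls(m)
  base <- pdist_encoded(idx_full, labels, min_sites, allele_aware)
  base_tree <- suppressMessages(nj_tree(base$d))
  splits <- tree_splits(base_tree)
  real <- !is.na(splits)
  counts <- setNames(rep(0L, sum(real)), splits[real])
  skipped <- 0L
  n_loci <- ncol(idx_full)
  withr::with_seed(seed, {
    for (r in seq_len(replicates)) {
      cols <- sample.int(n_loci, n_loci, replace = TRUE)
      rep_d <- tryCatch(
        pdist_encoded(idx_full[, cols, drop = FALSE], labels,
                      min_sites = 1, allele_aware = allele_aware),
        panelkin_too_few_sites = function(e) NULL
      )
      if (is.null(rep_d)) {
        skipped <- skipped + 1L
        next
      }
      rep_tree <- suppressMessages(nj_tree(rep_d$d))
      rep_keys <- tree_splits(rep_tree)
      hit <- names(counts) %in% rep_keys
      counts[hit] <- counts[hit] + 1L
    }
  })
  if (skipped > 0) {
    warn(sprintf(
      "bootstrap_support: %d of %d replicate(s) skipped (an accession pair had zero comparable sites)",
      skipped, replicates
    ))
  }
  evaluable <- replicates - skipped
  if (evaluable == 0) abort("no evaluable bootstrap replicates")
  support <- 100 * counts / evaluable
  node.label <- rep(NA_real_, base_tree$Nnode)
  ntip <- length(base_tree$tip.label)
  node.label[as.integer(names(splits)[real]) - ntip] <-
    support[splits[real]]
  base_tree$node.label <- node.label
  attr(base_tree, "bootstrap") <- list(replicates = replicates,
                                       skipped = skipped, seed = seed)
  base_tree
}
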