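# Neighbor joining (Saitou & Nei) with a fully deterministic tie-break:
# at each step the pair minimizing Q(i,j) = (n-2) d(i,j) - R_i - R_j is
# joined; equal minima are resolved by the lowest (row, column) index in
# the current node order (original label order, new nodes appended).
# Negative limb lengths are clamped to zero and flagged.

nj_limb_newick <- function(node, length) {
  sprintf("%s:%.17g", node, length)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Builds the unrooted NJ tree by Saitou-Nei agglomeration with the
#' standard limb-length and reduction formulas. On an additive distance
#' matrix the generating topology and branch lengths are recovered
#' exactly. Deterministic: ties in the Q criterion are broken by the
#' lowest (row, column) index pair, and negative limb lengths are clamped
#' to zero (a message reports how many).
#'
#' @param dm A [p_distance_matrix()] result, a [stats::dist], or a
#'   symmetric numeric matrix with dimnames.
#' @return An `ape::phylo` tree (unrooted, trifurcating root node).
#' @export
nj_tree <- function(dm) {
  D <- if (inherits(dm, "p_dist")) dm$d else as.matrix(dm)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  if (any(grepl("[(),:;]", labels))) {
    abort("taxon labels may not contain Newick metacharacters (),:;")
  }
  if (max(abs(D - t(D))) > 1e-12) abort("distance matrix must be symmetric")

  nodes <- labels
  clamped <- 0L
  while (n > 3) {
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    m <- min(Q)
    cand <- which(Q == m, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]
    j <- cand[1, 2]
    li <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { clamped <- clamped + 1L; li <- 0 }
    if (lj < 0) { clamped <- clamped + 1L; lj <- 0 }
    new_node <- sprintf("(%s,%s)", nj_limb_newick(nodes[i], li),
                        nj_limb_newick(nodes[j], lj))
    others <- setdiff(seq_len(n), c(i, j))
    new_d <- 0.5 * (D[i, others] + D[j, others] - D[i, j])
    D <- rbind(cbind(D[others, others, drop = FALSE], new_d),
               c(new_d, 0))
    nodes <- c(nodes[others], new_node)
    n <- n - 1
  }
  la <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  lb <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  lc <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  limbs <- c(la, lb, lc)
  clamped <- clamped + sum(limbs < 0)
  limbs[limbs < 0] <- 0
  if (clamped > 0) {
    inform(sprintf("nj_tree: clamped %d negative limb length(s) to 0",
                   clamped))
  }
  newick <- sprintf("(%s,%s,%s);",
                    nj_limb_newick(nodes[1], limbs[1]),
                    nj_limb_newick(nodes[2], limbs[2]),
                    nj_limb_newick(nodes[3], limbs[3]))
  ape::read.tree(text = newick)
}
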