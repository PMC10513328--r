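# Pairwise p-distances on genotype matrices with pairwise deletion of
# missing data. Calls are compared as literal characters by default; the
# allele-aware mode scores a heterozygote against a constituent homozygote
# as half a mismatch (1 - shared alleles / 2).

# Diploid call codes usable in distances; everything else (N and the 3/4-
# fold ambiguity letters) is treated as missing.
DIPLOID_CODES <- c(HOM_LETTERS, HET_LETTERS)

# 10x10 mismatch-weight matrix for the allele-aware mode.
allele_weight_matrix <- function() {
  pairs <- lapply(iupac_alleles(DIPLOID_CODES), function(a) {
    if (length(a) == 1) c(a, a) else a
  })
  W <- matrix(0, 10, 10, dimnames = list(DIPLOID_CODES, DIPLOID_CODES))
  for (i in 1:10) {
    for (j in 1:10) {
      tx <- table(pairs[[i]])
      ty <- table(pairs[[j]])
      common <- intersect(names(tx), names(ty))
      shared <- sum(pmin(tx[common], ty[common]))
      W[i, j] <- 1 - shared / 2
    }
  }
  W
}
ALLELE_W <- allele_weight_matrix()

# Encode a character call matrix as diploid-code indices (NA = missing).
encode_calls <- function(m) {
  idx <- match(m, DIPLOID_CODES)
  dim(idx) <- dim(m)
  idx
}

# Core pairwise computation on an encoded matrix. Returns list(d, n_comp)
# or aborts when a pair has fewer comparable sites than min_sites.
pdist_encoded <- function(idx, labels, min_sites, allele_aware) {
  n <- nrow(idx)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  n_comp <- matrix(ncol(idx), n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    xi <- idx[i, ]
    for (j in (i + 1):n) {
      yj <- idx[j, ]
      valid <- !is.na(xi) & !is.na(yj)
      comp <- sum(valid)
      if (comp < min_sites) {
        abort(sprintf(
          "pair '%s' / '%s' has only %d comparable site(s) (min_sites = %d)",
          labels[i], labels[j], comp, min_sites
        ), class = "panelkin_too_few_sites")
      }
      mism <- if (allele_aware) {
        sum(ALLELE_W[cbind(xi[valid], yj[valid])])
      } else {
        sum(xi[valid] != yj[valid])
      }
      d[i, j] <- d[j, i] <- mism / comp
      n_comp[i, j] <- n_comp[j, i] <- comp
    }
  }
  list(d = d, n_comp = n_comp)
}

#' Pairwise p-distance matrix of a genotype panel
#'
#' For each accession pair, sites where either call is missing (N or a
#' 3/4-fold ambiguity letter) are excluded and the distance is the fraction
#' of mismatching sites among those compared (pairwise deletion). By
#' default calls are compared strictly as characters; with
#' `allele_aware = TRUE` a heterozygote scores 0.5 against either of its
#' constituent homozygotes (and against a heterozygote sharing one allele).
#'
#' @param panel Genotype tibble (first column `accession`), or a sequence
#'   tibble (`id`, `sequence`) of equal-length pseudomolecules.
#' @param min_sites Minimum comparable sites per pair (default 50); a pair
#'   below it is an error naming the pair.
#' @param allele_aware Use allele-sharing mismatch weights (default FALSE).
#' @return An object of class `p_dist`: list with `labels`, `d` (symmetric
#'   matrix of fractions) and `n_comparable` (integer matrix of sites used
#'   per pair). Supports [as.matrix()], [stats::as.dist()], `tidy()`.
#' @export
p_distance_matrix <- function(panel, min_sites = 50, allele_aware = FALSE) {
  stopifnot(is.data.frame(panel))
  if (identical(names(panel), c("id", "sequence"))) {
    len <- unique(nchar(panel$sequence))
    if (length(len) != 1) abort("pseudomolecules must be equal length")
    m <- do.call(rbind, strsplit(panel$sequence, "", fixed = TRUE))
    rownames(m) <- panel$id
  } else {
    m <- geno_calls(panel)
  }
  if (nrow(m) < 2) abort("need at least 2 accessions")
  res <- pdist_encoded(encode_calls(m), rownames(m), min_sites, allele_aware)
  structure(
    list(labels = rownames(m), d = res$d, n_comparable = res$n_comp),
    class = "p_dist"
  )
}

#' @export
as.matrix.p_dist <- function(x, ...) x$d

#' @export
as.dist.p_dist <- function(m, ...) stats::as.dist(m$d)

#' @export
print.p_dist <- function(x, ...) {
  cat(sprintf("p-distance matrix: %d accessions\n", length(x$labels)))
  print(round(x$d, 4))
  invisible(x)
}

#' Tidy a p-distance matrix into pairwise rows
#'
#' @param x A `p_dist` object.
#' @param ... Unused.
#' @return Tibble with one row per unordered accession pair: `item1`,
#'   `item2`, `distance`, `n_comparable`.
#' @method tidy p_dist
#' @export
tidy.p_dist <- function(x, ...) {
  n <- length(x$labels)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(
    item1 = x$labels[idx[, 1]],
    item2 = x$labels[idx[, 2]],
    distance = x$d[idx],
    n_comparable = x$n_comparable[idx]
  )
}

#' Heatmap of a p-distance matrix
#'
#' @param object A `p_dist` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot p_dist
#' @export
autoplot.p_dist <- function(object, ...) {
  df <- tidy(object)
  df2 <- dplyr::bind_rows(
    df,
    dplyr::rename(df, item1 = "item2", item2 = "item1")
  )
  ggplot2::ggplot(df2, ggplot2::aes(
    x = factor(.data$item1, levels = object$labels),
    y = factor(.data$item2, levels = rev(object$labels)),
    fill = .data$distance
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "p-distance") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
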