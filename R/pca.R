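# PCA of morphological descriptor tables (CPVO/UPOV ordinal scores) for
# phenotypic placement of accessions, with variance-explained reporting
# and biplot coordinates. Built on stats::prcomp with a deterministic sign
# convention: per component, the largest-magnitude loading is positive.

#' Principal component analysis of a descriptor table
#'
#' Centers (and, by default, unit-scales) the descriptor columns and
#' decomposes them by SVD. Scaling is the default because ordinal
#' descriptor scores have heterogeneous ranges; pass `scale = FALSE` to
#' analyse the raw covariance. Component signs are fixed so the
#' largest-magnitude loading of each component is positive, making outputs
#' comparable across runs and implementations.
#'
#' @param table Descriptor tibble: first column `accession`, numeric
#'   descriptor columns, no missing cells, at least 3 accessions.
#' @param scale Unit-scale descriptors before decomposition (default
#'   TRUE); an error names any zero-variance descriptor.
#' @return Object of class `morpho_pca`: list with `scores` (tibble,
#'   `accession` + PC columns), `loadings` (tibble, `descriptor` + PC
#'   columns), `sdev`, `var_explained` (fractions, non-increasing, summing
#'   to 1) and `scaled`. Supports `tidy()`, `glance()`, `autoplot()`.
#' @export
pca_descriptors <- function(table, scale = TRUE) {
  validate_descriptors(table)
  x <- as.matrix(table[, -1, drop = FALSE])
  if (scale) {
    zero_var <- colnames(x)[apply(x, 2, sd) == 0]
    if (length(zero_var) > 0) {
      abort(sprintf(
        "descriptor '%s' has zero variance; drop it or use scale = FALSE",
        zero_var[1]
      ))
    }
  }
  fit <- prcomp(x, center = TRUE, scale. = scale)
  # sign convention: largest |loading| per component positive
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  fit$rotation <- sweep(fit$rotation, 2, flip, "*")
  fit$x <- sweep(fit$x, 2, flip, "*")
  var_explained <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(
      scores = dplyr::bind_cols(tibble(accession = table$accession),
                                as_tibble(fit$x)),
      loadings = dplyr::bind_cols(tibble(descriptor = colnames(x)),
                                  as_tibble(fit$rotation)),
      sdev = fit$sdev,
      center = fit$center,
      scale = fit$scale,
      var_explained = var_explained,
      scaled = scale
    ),
    class = "morpho_pca"
  )
}

#' Biplot coordinates for a pair of components
#'
#' Accession scores on the two requested components plus descriptor
#' arrows, the loadings scaled by the component standard deviations raised
#' to `arrow_exp` (1 gives covariance-style arrows, 0 raw loadings).
#'
#' @param result A `morpho_pca` object.
#' @param pcs Integer pair of component indices (default `c(1, 2)`).
#' @param arrow_exp Scaling exponent on the singular values (default 1).
#' @return List with `scores` (tibble `accession`, `x`, `y`) and `arrows`
#'   (tibble `descriptor`, `x`, `y`).
#' @export
biplot_coordinates <- function(result, pcs = c(1, 2), arrow_exp = 1) {
  stopifnot(inherits(result, "morpho_pca"), length(pcs) == 2)
  k <- length(result$sdev)
  if (any(pcs < 1 | pcs > k)) {
    abort(sprintf("component index out of range 1..%d", k))
  }
  pc_cols <- paste0("PC", pcs)
  scores <- tibble(
    accession = result$scores$accession,
    x = result$scores[[pc_cols[1]]],
    y = result$scores[[pc_cols[2]]]
  )
  sc <- result$sdev[pcs]^arrow_exp
  arrows <- tibble(
    descriptor = result$loadings$descriptor,
    x = result$loadings[[pc_cols[1]]] * sc[1],
    y = result$loadings[[pc_cols[2]]] * sc[2]
  )
  list(scores = scores, arrows = arrows)
}

#' @export
print.morpho_pca <- function(x, ...) {
  cat(sprintf(
    "PCA of %d accessions x %d descriptors (%s)\n",
    nrow(x$scores), nrow(x$loadings),
    if (x$scaled) "correlation" else "covariance"
  ))
  ve <- round(100 * x$var_explained[seq_len(min(5, length(x$sdev)))], 1)
  cat("  variance explained (%):", paste(ve, collapse = ", "),
      if (length(x$sdev) > 5) "..." else "", "\n")
  invisible(x)
}

#' Tidy the eigenvalue table of a descriptor PCA
#'
#' @param x A `morpho_pca` object.
#' @param ... Unused.
#' @return Tibble with `component`, `std_dev`, `var_explained`,
#'   `cumulative`.
#' @method tidy morpho_pca
#' @export
tidy.morpho_pca <- function(x, ...) {
  tibble(
    component = seq_along(x$sdev),
    std_dev = x$sdev,
    var_explained = x$var_explained,
    cumulative = cumsum(x$var_explained)
  )
}

#' @method glance morpho_pca
#' @export
glance.morpho_pca <- function(x, ...) {
  tibble(
    n_accessions = nrow(x$scores),
    n_descriptors = nrow(x$loadings),
    scaled = x$scaled,
    pc1_var = x$var_explained[1],
    pc2_var = x$var_explained[2]
  )
}

#' Biplot of a descriptor PCA
#'
#' @param object A `morpho_pca` object.
#' @param pcs Component pair to draw (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot object: accession scores as points, descriptor
#'   contributions as arrows.
#' @method autoplot morpho_pca
#' @export
autoplot.morpho_pca <- function(object, pcs = c(1, 2), ...) {
  bc <- biplot_coordinates(object, pcs)
  ve <- round(100 * object$var_explained[pcs], 1)
  arrow_scale <- max(abs(unlist(bc$scores[, c("x", "y")]))) /
    max(max(abs(unlist(bc$arrows[, c("x", "y")]))), .Machine$double.eps)
  arr <- dplyr::mutate(bc$arrows,
                       x = .data$x * arrow_scale * 0.8,
                       y = .data$y * arrow_scale * 0.8)
  ggplot2::ggplot(bc$scores, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_segment(
      data = arr,
      ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "firebrick", alpha = 0.7
    ) +
    ggplot2::geom_text(
      data = arr, ggplot2::aes(label = .data$descriptor),
      colour = "firebrick", size = 2.6, vjust = -0.4
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$accession),
                       size = 2.6, vjust = 1.6) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", pcs[1], ve[1]),
      y = sprintf("PC%d (%.1f%%)", pcs[2], ve[2])
    ) +
    ggplot2::theme_minimal()
}
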