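#' Principal-component analysis of a (merged) genotype matrix
#'
#' Standardizes every variant by its joint allele frequency — centring by
#' 2p and scaling by sqrt(2p(1-p)), the usual genotype standardization —
#' then extracts the top `n_pc` components by singular value decomposition.
#' Study and reference-panel samples are decomposed jointly (pass the
#' merged matrix from [align_to_reference()]), matching a joint-PCA design
#' where panel and study share one coordinate system.
#'
#' @param g a [geno_matrix()]; missing dosages are mean-imputed first.
#' @param n_pc number of components (default 10).
#' @return A list of class `pca_fit`: `scores` tibble (`id`, any sample
#'   metadata, `PC1..PCn`), `loadings` (M x n_pc), `center`, `scale`,
#'   `explained_var` (variance of each score), `n_pc`.
#' @export
fit_pca <- function(g, n_pc = 10) {
  g <- mean_impute(g)
  p <- colMeans(g$dosage) / 2
  keep <- p > 0 & p < 1
  d <- g$dosage[, keep, drop = FALSE]
  p <- p[keep]
  center <- 2 * p
  scale <- sqrt(2 * p * (1 - p))
  x <- sweep(sweep(d, 2, center, "-"), 2, scale, "/")
  r <- min(dim(x))
  if (n_pc > r) abort(sprintf("n_pc = %d exceeds matrix rank bound %d", n_pc, r))
  sv <- svd(x, nu = n_pc, nv = n_pc)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pc)], n_pc)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  out <- dplyr::bind_cols(g$samples, as_tibble(scores))
  structure(list(scores = out,
                 loadings = sv$v,
                 center = center, scale = scale,
                 variant_id = g$variants$id[keep],
                 explained_var = sv$d[seq_len(n_pc)]^2 / (nrow(x) - 1),
                 n_pc = n_pc),
            class = "pca_fit")
}

#' @export
print.pca_fit <- function(x, ...) {
  cat(sprintf("<pca_fit> %d samples, %d PCs\n", nrow(x$scores), x$n_pc))
  invisible(x)
}

#' Scatter plot of PCA scores
#'
#' @param object a `pca_fit`.
#' @param pcs which two components to draw.
#' @param colour_by name of a sample metadata column to colour by.
#' @param ... unused.
#' @method autoplot pca_fit
#' @export
autoplot.pca_fit <- function(object, pcs = c(1, 2), colour_by = NULL, ...) {
  xv <- paste0("PC", pcs[1]); yv <- paste0("PC", pcs[2])
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(x = .data[[xv]], y = .data[[yv]]))
  if (!is.null(colour_by)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]),
                                 alpha = 0.7, size = 1)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7, size = 1)
  }
  p + ggplot2::theme_minimal()
}
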