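#' Principal-component analysis of genotypes
#'
#' Standard genomic PCA: each SNP column is centred by `2*p` and scaled by
#' `sqrt(2*p*(1-p))` (the GRM convention; monomorphic SNPs are dropped),
#' and the individual scores are the leading eigenvectors of the resulting
#' individual-by-individual covariance, scaled by the singular values.
#' The sign of each component is fixed by making its largest-magnitude
#' SNP loading positive, so results are deterministic.
#'
#' @param gm a complete (no missing dosages) [genotype_matrix()]; impute
#'   first if needed.
#' @param n_components number of components to return (default 10, capped
#'   at `n_ind - 1`).
#' @return list of class `pca_result`: `scores` (individuals x components),
#'   `varprop` (proportion of total variance per component), `samples`.
#' @export
snp_pca <- function(gm, n_components = 10L) {
  if (anyNA(gm$dosage)) stop("missing dosages: impute before PCA")
  n <- n_ind(gm)
  if (n_components > n - 1L)
    stop("n_components must be at most n_individuals - 1")
  p <- allele_freq(gm)
  keep <- p > 0 & p < 1
  Z <- sweep(gm$dosage[, keep, drop = FALSE], 2, 2 * p[keep])
  Z <- sweep(Z, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  sv <- svd(Z, nu = n_components, nv = n_components)
  ev <- sv$d^2
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  for (k in seq_len(n_components)) {
    if (sv$v[which.max(abs(sv$v[, k])), k] < 0) scores[, k] <- -scores[, k]
  }
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(scores = scores, varprop = ev[seq_len(n_components)] / sum(ev),
                 samples = gm$samples),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " individuals x ", ncol(x$scores),
      " components\n  variance explained: ",
      paste(sprintf("%.1f%%", 100 * x$varprop), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Scatter plot of two principal components
#'
#' @param x a `pca_result`.
#' @param components which two PCs to plot (default 1:2).
#' @param ... passed to [graphics::plot()].
#' @export
plot.pca_result <- function(x, components = c(1L, 2L), ...) {
  f <- factor(x$samples$pop)
  i <- components[1]; j <- components[2]
  graphics::plot(x$scores[, i], x$scores[, j], col = as.integer(f), pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", i, 100 * x$varprop[i]),
                 ylab = sprintf("PC%d (%.1f%%)", j, 100 * x$varprop[j]), ...)
  graphics::legend("topright", legend = levels(f),
                   col = seq_along(levels(f)), pch = 19, bty = "n")
  invisible(x)
}
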