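#' Configuration for LD-based Ne estimation
#'
#' @param min_maf minimum minor-allele frequency for SNPs entering the
#'   pairwise r-squared computation (default 0.05).
#' @param bins distance bin edges in bp; default 13 geometric bins from
#'   50 kb to 25 Mb.
#' @param mapping physical-to-genetic mapping: `"linear"` (c = d Morgans),
#'   `"sved_feldman"` (hyperbolic, c = d / (1 + 2d)) or `"haldane"`
#'   (c = (1 - exp(-2d)) / 2), with d = bp distance converted via
#'   `cM_per_Mb`.
#' @param cM_per_Mb genetic map density (default 1, i.e. 1 Mb = 0.01 Morgan).
#' @param alpha_mut adjustment for the occurrence of mutation; 2.2 by the
#'   SNeP convention, 1 for mutation-free data (e.g. the package simulator).
#' @param mode sample-size correction: `"unphased"` subtracts
#'   `1/(2*n_ind)` from each r-squared, `"phased"` subtracts `1/n_hap`.
#' @param min_pairs bins with fewer pairs are flagged (default 50).
#' @return list of class `ne_config`.
#' @export
ne_config <- function(min_maf = 0.05,
                      bins = exp(seq(log(5e4), log(2.5e7), length.out = 14)),
                      mapping = c("linear", "sved_feldman", "haldane"),
                      cM_per_Mb = 1, alpha_mut = 2.2,
                      mode = c("unphased", "phased"), min_pairs = 50L) {
  stopifnot(all(diff(bins) > 0), alpha_mut >= 1)
  structure(list(min_maf = min_maf, bins = bins,
                 mapping = match.arg(mapping), cM_per_Mb = cM_per_Mb,
                 alpha_mut = alpha_mut, mode = match.arg(mode),
                 min_pairs = as.integer(min_pairs)),
            class = "ne_config")
}

#' Map physical distance to recombination rate
#'
#' @param dist_bp physical distance in bp.
#' @param mapping,cM_per_Mb see [ne_config()].
#' @return recombination rate c in Morgans.
#' @export
recomb_rate <- function(dist_bp, mapping = "linear", cM_per_Mb = 1) {
  d <- dist_bp * cM_per_Mb * 1e-8   # Morgans
  switch(mapping,
         linear = d,
         sved_feldman = d / (1 + 2 * d),
         haldane = (1 - exp(-2 * d)) / 2,
         stop("unknown mapping: ", mapping))
}

#' Pairwise r-squared within a chromosome
#'
#' Squared Pearson correlation of dosages (unphased mode, one population's
#' genotype rows) or of binary haplotype alleles (phased mode) for every
#' intra-chromosomal SNP pair within `max_dist_bp`. Missing genotypes are
#' excluded pairwise; pairs involving a zero-variance SNP are skipped.
#'
#' @param x a [genotype_matrix()] or [haplotype_panel()].
#' @param chrom chromosome to use.
#' @param max_dist_bp maximum pair distance (default 25 Mb).
#' @param pop optional population label to restrict individuals.
#' @param min_maf MAF filter applied before pairing (default 0.05).
#' @return data.frame with `dist_bp`, `r2`, `n_used` (individuals for
#'   unphased input, haplotypes for phased input).
#' @export
pairwise_r2 <- function(x, chrom, max_dist_bp = 2.5e7, pop = NULL,
                        min_maf = 0.05) {
  phased <- inherits(x, "haplotype_panel")
  cols <- which(x$snps$chrom == chrom)
  if (phased) {
    mat <- x$hap
    if (!is.null(pop)) {
      k <- which(x$samples$pop == pop)
      mat <- mat[as.vector(rbind(2L * k - 1L, 2L * k)), , drop = FALSE]
    }
  } else {
    mat <- x$dosage
    if (!is.null(pop)) mat <- mat[x$samples$pop == pop, , drop = FALSE]
  }
  mat <- mat[, cols, drop = FALSE]
  bp <- x$snps$bp[cols]
  p <- colMeans(mat, na.rm = TRUE) / (if (phased) 1 else 2)
  maf <- pmin(p, 1 - p)
  keep <- !is.nan(maf) & maf >= min_maf
  v <- apply(mat, 2, stats::var, na.rm = TRUE)
  keep <- keep & !is.na(v) & v > 0
  mat <- mat[, keep, drop = FALSE]
  bp <- bp[keep]
  m <- ncol(mat)
  if (m < 2L)
    return(data.frame(dist_bp = numeric(), r2 = numeric(), n_used = integer()))
  cc <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
  nobs <- crossprod(!is.na(mat))
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  dist <- bp[idx[, 2]] - bp[idx[, 1]]
  ok <- dist <= max_dist_bp & is.finite(cc[idx])
  data.frame(dist_bp = dist[ok],
             r2 = cc[idx][ok]^2,
             n_used = as.integer(nobs[idx][ok]))
}

#' Sample-size adjustment of r-squared
#'
#' Removes the finite-sample inflation: phased data subtract `1/n` (n =
#' haplotypes), unphased subtract `1/(2*n)` (n = individuals). Negative
#' adjusted values are kept so that bin means stay unbiased.
#'
#' @param r2 raw r-squared values.
#' @param n sample sizes (haplotypes or individuals, per value or scalar).
#' @param mode `"phased"` or `"unphased"`.
#' @return adjusted r-squared values.
#' @export
adjust_r2 <- function(r2, n, mode = c("unphased", "phased")) {
  mode <- match.arg(mode)
  stopifnot(all(n >= 2))
  r2 - switch(mode, phased = 1 / n, unphased = 1 / (2 * n))
}

#' Estimate the historical Ne trajectory from binned LD
#'
#' Pairs are grouped into distance bins; per bin, the recombination rate
#' `c_t` is mapped from the mean pair distance, the time point is
#' `t = 1/(2 c_t)` generations ago, and the size estimate inverts the
#' drift-LD relation:
#' `N_t = (1 / (4 c_t)) * (1 / mean(r2_adj) - alpha_mut)`.
#' Bins with too few pairs or with non-positive `1/mean - alpha` are flagged
#' (`valid = FALSE`), never silently dropped.
#'
#' @param records data.frame from [pairwise_r2()].
#' @param config a [ne_config()].
#' @return data.frame of class `ne_trajectory` with one row per bin:
#'   `dist_bp` (mean pair distance), `c_t`, `gens_ago`, `mean_r2_adj`,
#'   `n_pairs`, `ne`, `valid`.
#' @export
estimate_ne <- function(records, config = ne_config()) {
  r2a <- adjust_r2(records$r2, records$n_used, config$mode)
  bin <- cut(records$dist_bp, breaks = config$bins, right = FALSE)
  rows <- lapply(levels(bin), function(lv) {
    sel <- !is.na(bin) & bin == lv
    n <- sum(sel)
    if (n == 0L)
      return(data.frame(dist_bp = NA_real_, c_t = NA_real_, gens_ago = NA_real_,
                        mean_r2_adj = NA_real_, n_pairs = 0L, ne = NA_real_,
                        valid = FALSE))
    dm <- mean(records$dist_bp[sel])
    ct <- recomb_rate(dm, config$mapping, config$cM_per_Mb)
    mr <- mean(r2a[sel])
    inv <- if (mr > 0) 1 / mr - config$alpha_mut else NA_real_
    ne <- if (!is.na(inv) && inv > 0) inv / (4 * ct) else NA_real_
    data.frame(dist_bp = dm, c_t = ct, gens_ago = 1 / (2 * ct),
               mean_r2_adj = mr, n_pairs = n, ne = ne,
               valid = !is.na(ne) && n >= config$min_pairs)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  class(out) <- c("ne_trajectory", class(out))
  out
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("<ne_trajectory> (", sum(x$valid), " valid of ", nrow(x), " bins; mapping ",
      attr(x, "config")$mapping, ", alpha ", attr(x, "config")$alpha_mut, ")\n",
      sep = "")
  print.data.frame(format(as.data.frame(x), digits = 4))
  invisible(x)
}

#' Plot an Ne trajectory
#'
#' Estimated Ne against generations ago (log-x), valid bins only.
#'
#' @param x a `ne_trajectory` (or a named list of them, via `lines`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ne_trajectory <- function(x, ...) {
  ok <- x$valid
  graphics::plot(x$gens_ago[ok], x$ne[ok], log = "x", type = "b", pch = 19,
                 xlab = "generations ago", ylab = "estimated Ne", ...)
  invisible(x)
}

#' Write an Ne trajectory as TSV
#' @param traj a `ne_trajectory`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ne_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
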