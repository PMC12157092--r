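#' Two-population Weir-Cockerham theta
#'
#' Variance-components estimator of FST for one biallelic SNP from
#' per-population summaries: sample sizes `n1`, `n2` (individuals with
#' observed genotypes), allele frequencies `p1`, `p2` and observed
#' heterozygote proportions `h1`, `h2`. Vectorised over SNPs. The estimate
#' may be negative; it is `NA` (flagged) when the total variance `a+b+c`
#' is zero (both populations fixed for the same allele).
#'
#' @param n1,p1,h1,n2,p2,h2 per-SNP summaries (recycled as needed).
#' @return numeric vector of theta-hat values.
#' @export
wc_fst <- function(n1, p1, h1, n2, p2, h2) {
  stopifnot(all(n1 >= 2), all(n2 >= 2))
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  tot <- a + b + cc
  out <- a / tot
  out[tot == 0] <- NA_real_
  out
}

#' Per-SNP Weir-Cockerham FST for a two-population genotype matrix
#'
#' @param gm a [genotype_matrix()] with exactly two population labels.
#' @param pops optional character(2) selecting/ordering the two populations.
#' @return data.frame with `id`, `chrom`, `bp`, `fst` (NA where undefined).
#' @export
fst_per_snp <- function(gm, pops = NULL) {
  if (is.null(pops)) pops <- unique(gm$samples$pop)
  stopifnot(length(pops) == 2)
  summ <- lapply(pops, function(pp) {
    d <- gm$dosage[gm$samples$pop == pp, , drop = FALSE]
    n <- colSums(!is.na(d))
    list(n = n, p = colMeans(d, na.rm = TRUE) / 2,
         h = colSums(d == 1L, na.rm = TRUE) / n)
  })
  ok <- summ[[1]]$n >= 2 & summ[[2]]$n >= 2
  fst <- rep(NA_real_, n_snp(gm))
  fst[ok] <- wc_fst(summ[[1]]$n[ok], summ[[1]]$p[ok], summ[[1]]$h[ok],
                    summ[[2]]$n[ok], summ[[2]]$p[ok], summ[[2]]$h[ok])
  data.frame(id = gm$snps$id, chrom = gm$snps$chrom, bp = gm$snps$bp,
             fst = fst, stringsAsFactors = FALSE)
}

#' Gaussian kernel smoothing along a chromosome
#'
#' Nadaraya-Watson local-constant regression with a Gaussian kernel,
#' evaluated at each SNP position. `NA` values are excluded from both
#' numerator and denominator. A single SNP (or `bandwidth_bp = 0`) returns
#' the raw values.
#'
#' @param values statistic per SNP (NA allowed).
#' @param positions_bp sorted bp positions.
#' @param bandwidth_bp Gaussian sigma in bp; `NULL` uses a plug-in
#'   rule-of-thumb (Silverman's factor on the position spacing scale; see
#'   [rot_bandwidth()]).
#' @return smoothed values (NA inputs get smoothed predictions too).
#' @export
kernel_smooth <- function(values, positions_bp, bandwidth_bp = NULL) {
  m <- length(values)
  stopifnot(length(positions_bp) == m)
  if (m <= 1L) return(values)
  if (is.null(bandwidth_bp)) bandwidth_bp <- rot_bandwidth(positions_bp)
  if (bandwidth_bp <= 0) return(values)
  obs <- which(!is.na(values))
  if (!length(obs)) return(values)
  out <- numeric(m)
  # chunked to bound the m x m kernel matrix
  chunk <- max(1L, floor(2e6 / length(obs)))
  for (st in seq(1L, m, by = chunk)) {
    en <- min(m, st + chunk - 1L)
    w <- exp(-0.5 * (outer(positions_bp[st:en], positions_bp[obs], "-") /
                       bandwidth_bp)^2)
    out[st:en] <- (w %*% values[obs]) / rowSums(w)
  }
  out
}

#' Rule-of-thumb smoothing bandwidth
#'
#' Local-scale plug-in: `k` times the median inter-SNP spacing on the
#' chromosome (default `k = 5`). Tying the kernel scale to marker density
#' keeps the effective averaging window at a dozen or so SNPs — enough to
#' suppress single-SNP noise without flattening selection peaks, which span
#' tens to hundreds of kb, not megabases.
#'
#' @param positions_bp sorted positions.
#' @param k multiple of the median spacing (default 5).
#' @return bandwidth in bp.
#' @export
rot_bandwidth <- function(positions_bp, k = 5) {
  m <- length(positions_bp)
  if (m < 2L) return(0)
  k * stats::median(diff(positions_bp))
}

#' Block means over consecutive SNPs
#'
#' Averages each set of `w` adjacent values into one windowed value
#' (non-overlapping blocks, per chromosome); a trailing remainder block of
#' fewer than `w` SNPs is kept. The block value sits at the mean position of
#' its member SNPs.
#'
#' @param values per-SNP statistic.
#' @param w window size in SNPs (default 5).
#' @return list with `values` (block means, NA-aware), `block` (block index
#'   per SNP).
#' @export
windowed_mean <- function(values, w = 5L) {
  stopifnot(w >= 1)
  m <- length(values)
  block <- (seq_len(m) - 1L) %/% w + 1L
  means <- tapply(values, block, mean, na.rm = TRUE)
  list(values = as.numeric(means), block = block)
}

#' Flag values above an empirical percentile
#'
#' The genome-wide threshold is the empirical `percentile` quantile of the
#' finite values; values strictly above it are flagged. With fewer than 1000
#' finite values the 99.9th percentile is not meaningful and a warning is
#' given.
#'
#' @param values statistic values (NA ignored, never flagged).
#' @param percentile quantile level (default 0.999).
#' @return list with `flag` (logical), `threshold`.
#' @export
call_signatures <- function(values, percentile = 0.999) {
  fin <- is.finite(values)
  if (sum(fin) < 1000)
    warning("fewer than 1000 values: the ", percentile,
            " percentile threshold is unstable")
  thr <- stats::quantile(values[fin], percentile, names = FALSE)
  flag <- !is.na(values) & fin & values > thr
  list(flag = flag, threshold = thr)
}

#' Windowed Weir-Cockerham FST genome scan
#'
#' Computes raw per-SNP theta-hat, Gaussian-kernel smoothed values per
#' chromosome, then non-overlapping `window_snps`-SNP block means of the
#' smoothed track ("windowed FST"), and flags windows strictly above the
#' genome-wide `percentile` threshold of windowed values. Negative raw
#' estimates are retained (truncation would bias window means); SNPs with
#' undefined theta are excluded from smoothing and the percentile.
#'
#' @param gm two-population [genotype_matrix()].
#' @param window_snps SNPs per window (default 5).
#' @param bandwidth_bp smoothing bandwidth; `NULL` = per-chromosome plug-in
#'   rule of thumb.
#' @param percentile signature threshold quantile (default 0.999).
#' @param window_input `"smoothed"` (default) or `"raw"`: which track the
#'   windowed means are computed from.
#' @param pops optional character(2) population selection.
#' @return list of class `fst_scan`: `snp` (per-SNP data.frame with `fst`,
#'   `smoothed`, `window`), `window` (per-window data.frame with `chrom`,
#'   `bp` midpoint, `n_snps`, `fst_win`, `flag`), `threshold`, `bandwidth`.
#' @export
fst_scan <- function(gm, window_snps = 5L, bandwidth_bp = NULL,
                     percentile = 0.999, window_input = c("smoothed", "raw"),
                     pops = NULL) {
  window_input <- match.arg(window_input)
  snp <- fst_per_snp(gm, pops)
  snp$smoothed <- NA_real_
  snp$window <- NA_integer_
  bws <- c()
  win_rows <- list()
  wid0 <- 0L
  for (ch in unique(snp$chrom)) {
    sel <- which(snp$chrom == ch)
    bw <- if (is.null(bandwidth_bp)) rot_bandwidth(snp$bp[sel]) else bandwidth_bp
    bws[as.character(ch)] <- bw
    snp$smoothed[sel] <- kernel_smooth(snp$fst[sel], snp$bp[sel], bw)
    base <- if (window_input == "smoothed") snp$smoothed[sel] else snp$fst[sel]
    wm <- windowed_mean(base, window_snps)
    snp$window[sel] <- wid0 + wm$block
    win_rows[[length(win_rows) + 1L]] <- data.frame(
      window = wid0 + seq_along(wm$values), chrom = ch,
      bp = as.numeric(tapply(snp$bp[sel], wm$block, mean)),
      n_snps = as.integer(table(wm$block)),
      fst_win = wm$values)
    wid0 <- wid0 + length(wm$values)
  }
  win <- do.call(rbind, win_rows)
  cs <- call_signatures(win$fst_win, percentile)
  win$flag <- cs$flag
  structure(list(snp = snp, window = win, threshold = cs$threshold,
                 bandwidth = bws, window_input = window_input,
                 percentile = percentile),
            class = "fst_scan")
}

#' @export
print.fst_scan <- function(x, ...) {
  cat("<fst_scan> ", nrow(x$snp), " SNPs, ", nrow(x$window), " windows (",
      x$window_input, " -> windowed)\n", sep = "")
  cat(sprintf("  threshold (p=%.4g): %.4g; %d windows flagged\n",
              x$percentile, x$threshold, sum(x$window$flag)))
  invisible(x)
}
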