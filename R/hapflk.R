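#' Reynolds coancestry distance between two populations
#'
#' The classical least-squares coancestry distance aggregated over SNPs:
#' `D = sum_l (p_A - p_B)^2 / sum_l (1 - p_A p_B - q_A q_B)`. Identical
#' frequencies give 0; a fixed difference at every SNP gives 1.
#'
#' @param p_A,p_B allele frequencies per SNP in the two populations.
#' @return scalar distance in `[0, 1]`.
#' @export
reynolds_distance <- function(p_A, p_B) {
  stopifnot(length(p_A) == length(p_B))
  ok <- is.finite(p_A) & is.finite(p_B)
  num <- sum((p_A[ok] - p_B[ok])^2)
  den <- sum(1 - p_A[ok] * p_B[ok] - (1 - p_A[ok]) * (1 - p_B[ok]))
  if (den <= 0) return(0)
  num / den
}

#' Two-population kinship matrix from a Reynolds distance
#'
#' With only two populations and no outgroup the per-branch drifts cannot be
#' separated, and the Reynolds estimator measures the average per-population
#' drift since the split. The kinship diagonal is therefore set to that
#' average, `f_A = f_B = D`, with zero off-diagonals — the unique symmetric
#' assignment under which the drift-corrected frequency contrast is
#' chi-squared with 1 degree of freedom under neutrality (see the methods
#' vignette for the derivation). `D = 0` is degenerate (no drift to scale
#' against) and is flagged.
#'
#' @param D Reynolds distance from [reynolds_distance()].
#' @param pop_names names for the two populations.
#' @return list of class `kinship_model`: `D`, `F` (2x2 matrix),
#'   `degenerate`.
#' @export
build_kinship <- function(D, pop_names = c("A", "B")) {
  stopifnot(D >= 0)
  F <- diag(c(D, D))
  dimnames(F) <- list(pop_names, pop_names)
  structure(list(D = D, F = F, degenerate = D == 0),
            class = "kinship_model")
}

#' @export
print.kinship_model <- function(x, ...) {
  cat("<kinship_model> Reynolds D =", format(x$D, digits = 4),
      if (x$degenerate) "(degenerate)" else "", "\n")
  print(x$F)
  invisible(x)
}

#' FLK statistic per SNP
#'
#' Drift-corrected allele-frequency differentiation: the ancestral frequency
#' is the generalized-least-squares mean
#' `p0 = (1' F^-1 p) / (1' F^-1 1)` and
#' `FLK = (p - p0 1)' V^-1 (p - p0 1)` with `V = p0 (1 - p0) F`.
#' SNPs where `p0` is 0 or 1 (monomorphic overall) are flagged `NA`.
#'
#' @param p_hat matrix of sample allele frequencies, populations in rows,
#'   SNPs in columns (or a length-2 vector for one SNP).
#' @param kinship a [build_kinship()] result (or a plain positive-definite
#'   matrix).
#' @return numeric vector of FLK values per SNP (NA where flagged).
#' @export
flk <- function(p_hat, kinship) {
  F <- if (inherits(kinship, "kinship_model")) kinship$F else kinship
  if (is.vector(p_hat)) p_hat <- matrix(p_hat, ncol = 1)
  stopifnot(nrow(p_hat) == nrow(F))
  if (inherits(kinship, "kinship_model") && kinship$degenerate)
    return(rep(NA_real_, ncol(p_hat)))
  A <- solve(F)
  s <- sum(A)
  p0 <- colSums(A %*% p_hat) / s
  dev <- sweep(p_hat, 2, p0)
  quad <- colSums(dev * (A %*% dev))
  out <- quad / (p0 * (1 - p0))
  out[p0 <= 0 | p0 >= 1] <- NA_real_
  out
}

#' Fit the haplotype-cluster LD model by EM
#'
#' A fastPHASE-style hidden Markov model over phased haplotypes: hidden
#' cluster states along each haplotype, per-SNP per-cluster allele
#' frequencies as emissions, and a per-interval cluster-switch rate with
#' per-SNP jump destination weights as transitions. Both populations are
#' pooled for fitting. The EM log-likelihood is non-decreasing across
#' iterations; the fit stops at `max_iter` iterations or a relative
#' log-likelihood change below `tol`.
#'
#' @param panel a phased [haplotype_panel()] (or a 0/1 matrix).
#' @param K number of clusters (default 2).
#' @param rho_init initial switch rate per interval (uniform; default 0.05).
#' @param seed RNG seed for the perturbed-pooled-frequency initialization of
#'   the emission probabilities.
#' @param max_iter,tol EM stopping rule (defaults 50 and 1e-6 relative).
#' @return list of class `hap_cluster_model`: `theta` (m x K), `rho` (m),
#'   `w` (m x K jump weights), `gamma` (n_hap x m x K posterior
#'   memberships), `loglik`, `loglik_trace`, `n_iter`, `K`.
#' @export
fit_hap_clusters <- function(panel, K = 2L, rho_init = 0.05, seed = 1L,
                             max_iter = 50L, tol = 1e-6) {
  hap <- if (inherits(panel, "haplotype_panel")) panel$hap else as.matrix(panel)
  storage.mode(hap) <- "integer"
  if (K > nrow(hap)) stop("K exceeds the number of haplotypes")
  m <- ncol(hap)
  withr_seed(seed, {
    pool <- pmin(pmax(colMeans(hap), 0.05), 0.95)
    theta0 <- matrix(pool, m, K) +
      matrix(stats::runif(m * K, -0.05, 0.05), m, K)
    theta0 <- pmin(pmax(theta0, 1e-3), 1 - 1e-3)
  })
  fit <- .hmm_cluster_em(hap, as.integer(K), theta0, rep(rho_init, m),
                         as.integer(max_iter), tol)
  fit$K <- K
  class(fit) <- "hap_cluster_model"
  fit
}

#' @export
print.hap_cluster_model <- function(x, ...) {
  cat("<hap_cluster_model> K =", x$K, ", loglik =",
      format(x$loglik, digits = 8), "after", x$n_iter, "EM iterations\n")
  invisible(x)
}

# per-SNP hapFLK for one fitted model: FLK-form quadratic on the stacked
# (K-1 free) population cluster frequencies
.hapflk_one <- function(gamma, pop_of_hap, kinship) {
  dims <- dim(gamma)
  m <- dims[2]; K <- dims[3]
  pops <- rownames(kinship$F)
  fdiag <- diag(kinship$F)
  # population cluster frequencies: q[pop, j, k]
  q <- array(NA_real_, c(length(pops), m, K))
  for (pi in seq_along(pops)) {
    rows <- which(pop_of_hap == pops[pi])
    for (k in seq_len(K))
      q[pi, , k] <- colMeans(gamma[rows, , k, drop = FALSE])
  }
  if (K == 2L) {
    # one free cluster frequency: fully vectorised over SNPs
    q1 <- q[, , 1, drop = TRUE]            # pops x m
    q0 <- colMeans(q1)
    S <- q0 * (1 - q0)
    dev2 <- sweep(q1, 2, q0)^2 / fdiag
    out <- colSums(dev2) / S
    out[S <= 0] <- NA_real_
    return(out)
  }
  out <- numeric(m)
  for (j in seq_len(m)) {
    q0 <- colMeans(q[, j, ])           # equal kinship: GLS mean = plain mean
    kk <- seq_len(K - 1L)
    S <- diag(q0[kk], nrow = K - 1L) - tcrossprod(q0[kk])
    Si <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(Si)) { out[j] <- NA_real_; next }
    acc <- 0
    for (pi in seq_along(pops)) {
      d <- q[pi, j, kk] - q0[kk]
      acc <- acc + (d %*% Si %*% d) / fdiag[pi]
    }
    out[j] <- as.numeric(acc)
  }
  out
}

#' hapFLK statistic averaged over EM fits
#'
#' For each EM fit, population-level cluster frequencies are computed from
#' the posterior memberships and contrasted with the FLK quadratic form
#' (kinship-scaled, on the K-1 free cluster frequencies); the final
#' statistic is the mean over the fits.
#'
#' @param fits list of [fit_hap_clusters()] models (>= 1).
#' @param pop_of_hap population label per haplotype row.
#' @param kinship a [build_kinship()] result.
#' @return numeric vector: hapFLK per SNP.
#' @export
hapflk_statistic <- function(fits, pop_of_hap, kinship) {
  stopifnot(length(fits) >= 1)
  vals <- sapply(fits, function(f) .hapflk_one(f$gamma, pop_of_hap, kinship))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  rowMeans(vals)
}

#' Fit a null distribution and call hapFLK signatures
#'
#' The genome-wide hapFLK distribution is matched to a scaled chi-squared
#' null by robust quantile fitting on the central 90% (probabilities 0.05 to
#' 0.95): the degrees of freedom and scale minimize the squared distance
#' between empirical and theoretical quantiles. P-values come from the
#' fitted null, q-values from Benjamini-Hochberg, and SNPs with
#' `q < q_threshold` are flagged.
#'
#' @param values per-SNP hapFLK values (NA ignored, never flagged).
#' @param q_threshold FDR threshold (default 0.01).
#' @return data.frame `hapflk`, `p`, `q`, `flag` plus attributes `scale`,
#'   `df`.
#' @export
call_hapflk <- function(values, q_threshold = 0.01) {
  fin <- which(is.finite(values))
  if (length(fin) < 1000)
    warning("fewer than 1000 hapFLK values: null fit is unstable")
  probs <- seq(0.05, 0.95, by = 0.05)
  Q <- stats::quantile(values[fin], probs, names = FALSE)
  fit_s <- function(k) {
    qq <- stats::qchisq(probs, df = k)
    sum(Q * qq) / sum(qq^2)
  }
  obj <- function(k) {
    s <- fit_s(k)
    sum((Q - s * stats::qchisq(probs, df = k))^2)
  }
  k <- stats::optimize(obj, c(0.05, 50))$minimum
  s <- fit_s(k)
  p <- rep(NA_real_, length(values))
  p[fin] <- stats::pchisq(values[fin] / s, df = k, lower.tail = FALSE)
  q <- rep(NA_real_, length(values))
  q[fin] <- stats::p.adjust(p[fin], method = "BH")
  out <- data.frame(hapflk = values, p = p, q = q,
                    flag = !is.na(q) & q < q_threshold)
  attr(out, "scale") <- s
  attr(out, "df") <- k
  out
}

#' Full FLK + hapFLK genome scan
#'
#' Computes per-population allele frequencies, the Reynolds distance and
#' two-population kinship, per-SNP FLK, `nfit` seeded EM fits of the
#' haplotype-cluster model, the fit-averaged hapFLK, and q-value calls.
#'
#' @param gm a two-population [genotype_matrix()] (for allele frequencies).
#' @param panel the matching phased [haplotype_panel()].
#' @param K haplotype clusters (default 2).
#' @param nfit number of EM fits averaged (default 20).
#' @param q_threshold FDR significance threshold (default 0.01).
#' @param seed root seed; fit i uses `seed + i`.
#' @param max_iter,tol EM stopping rule per fit.
#' @return list of class `hapflk_scan`: `track` (per-SNP data.frame with
#'   `id`, `chrom`, `bp`, `flk`, `hapflk`, `p`, `q`, `flag`), `kinship`,
#'   `nfit`, `null` (scale/df of the fitted null).
#' @export
hapflk_scan <- function(gm, panel, K = 2L, nfit = 20L, q_threshold = 0.01,
                        seed = 1L, max_iter = 50L, tol = 1e-6) {
  pops <- unique(gm$samples$pop)
  stopifnot(length(pops) == 2)
  pA <- allele_freq(gm, pops[1])
  pB <- allele_freq(gm, pops[2])
  kin <- build_kinship(reynolds_distance(pA, pB), pops)
  flk_vals <- flk(rbind(pA, pB), kin)
  fits <- lapply(seq_len(nfit), function(i)
    fit_hap_clusters(panel, K = K, seed = seed + i,
                     max_iter = max_iter, tol = tol))
  pop_of_hap <- rep(panel$samples$pop, each = 2L)
  hf <- hapflk_statistic(fits, pop_of_hap, kin)
  calls <- call_hapflk(hf, q_threshold)
  track <- data.frame(id = gm$snps$id, chrom = gm$snps$chrom, bp = gm$snps$bp,
                      flk = flk_vals, hapflk = hf, p = calls$p, q = calls$q,
                      flag = calls$flag, stringsAsFactors = FALSE)
  structure(list(track = track, kinship = kin, nfit = nfit,
                 null = c(scale = attr(calls, "scale"), df = attr(calls, "df")),
                 q_threshold = q_threshold),
            class = "hapflk_scan")
}

#' @export
print.hapflk_scan <- function(x, ...) {
  cat("<hapflk_scan> ", nrow(x$track), " SNPs, ", x$nfit, " EM fits, D = ",
      format(x$kinship$D, digits = 4), "\n", sep = "")
  cat(sprintf("  null: %.3g * chisq(df=%.2f); %d SNPs at q < %g\n",
              x$null["scale"], x$null["df"], sum(x$track$flag, na.rm = TRUE),
              x$q_threshold))
  invisible(x)
}
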