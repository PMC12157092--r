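#' Extended haplotype homozygosity from a core SNP
#'
#' For each SNP j moving away from the core, EHH(j) is the probability that
#' two randomly drawn haplotypes are identical at every SNP from the core
#' through j: `sum_h C(n_h, 2) / C(n, 2)` over the groups of identical
#' prefixes. All haplotypes are pooled and the core allele is not
#' partitioned (the cross-population convention); EHH is therefore
#' allele-polarity-free.
#'
#' @param hap 0/1 haplotype matrix (rows = haplotypes) for one chromosome.
#' @param core_idx core SNP column.
#' @param direction `"left"` or `"right"`.
#' @param positions_bp per-column positions (for the distance field).
#' @param stop_below stop extending once EHH drops below this (default 0,
#'   i.e. run to the chromosome end).
#' @param groups optional starting group assignment (used internally to
#'   share grouping between pooled and per-population curves).
#' @return data.frame of class `ehh_curve`: `snp` (column index), `dist_bp`,
#'   `ehh`; first row is the core itself (distance 0, EHH 1).
#' @export
ehh <- function(hap, core_idx, direction = c("right", "left"),
                positions_bp = NULL, stop_below = 0) {
  direction <- match.arg(direction)
  n <- nrow(hap)
  m <- ncol(hap)
  if (is.null(positions_bp)) positions_bp <- seq_len(m)
  step <- if (direction == "right") 1L else -1L
  js <- seq(core_idx, if (direction == "right") m else 1L, by = step)
  denom <- n * (n - 1) / 2
  out_snp <- integer(length(js)); out_ehh <- numeric(length(js))
  # distance 0: EHH = 1 by convention; the core allele joins the prefix
  # grouping from the first flanking SNP on
  g <- match(hap[, core_idx], unique(hap[, core_idx]))
  out_snp[1] <- core_idx; out_ehh[1] <- 1
  k <- 1L
  for (j in js[-1]) {
    key <- g * 2L + hap[, j]
    g <- match(key, unique(key))
    sz <- tabulate(g)
    e <- sum(sz * (sz - 1) / 2) / denom
    k <- k + 1L
    out_snp[k] <- j; out_ehh[k] <- e
    if (e < stop_below) break
  }
  out <- data.frame(snp = out_snp[1:k],
                    dist_bp = abs(positions_bp[out_snp[1:k]] - positions_bp[core_idx]),
                    ehh = out_ehh[1:k])
  class(out) <- c("ehh_curve", class(out))
  out
}

# grouped EHH for pooled + two subsets simultaneously, stopping when the
# POOLED curve falls below `trunc`; returns per-arm trapezoid integrals.
.arm_ihh <- function(hapA, hapB, core_idx, direction, bp, trunc = 0.05) {
  nA <- nrow(hapA); nB <- nrow(hapB)
  hap <- rbind(hapA, hapB)
  n <- nA + nB
  m <- ncol(hap)
  step <- if (direction == "right") 1L else -1L
  last <- if (direction == "right") m else 1L
  js <- seq(core_idx, last, by = step)
  ia <- seq_len(nA); ib <- nA + seq_len(nB)
  dP <- n * (n - 1) / 2; dA <- nA * (nA - 1) / 2; dB <- nB * (nB - 1) / 2
  eP <- eA <- eB <- numeric(length(js))
  dist <- abs(bp[js] - bp[core_idx])
  g <- match(hap[, core_idx], unique(hap[, core_idx]))
  eP[1] <- eA[1] <- eB[1] <- 1   # distance 0
  k <- 1L
  truncated <- FALSE
  for (j in js[-1]) {
    key <- g * 2L + hap[, j]
    g <- match(key, unique(key))
    k <- k + 1L
    szP <- tabulate(g)
    eP[k] <- sum(szP * (szP - 1) / 2) / dP
    szA <- tabulate(g[ia]); szB <- tabulate(g[ib])
    eA[k] <- sum(szA * (szA - 1) / 2) / dA
    eB[k] <- sum(szB * (szB - 1) / 2) / dB
    if (eP[k] < trunc) { truncated <- TRUE; break }
  }
  trap <- function(e) {
    if (k < 2L) return(0)
    d <- dist[1:k]
    sum((e[1:(k - 1)] + e[2:k]) / 2 * abs(diff(d)))
  }
  list(ihh_a = trap(eA), ihh_b = trap(eB), truncated = truncated)
}

#' Integrated EHH for one core, both arms, shared truncation
#'
#' EHH of the combined two-population sample is extended left and right from
#' the core until it drops below `trunc` (default 0.05); each population's
#' own EHH curve is integrated (trapezoid rule over physical distance) from
#' the core to that shared truncation point, and the two arms are summed.
#' Cores whose combined EHH never falls below `trunc` before a chromosome
#' end are flagged `edge_truncated`.
#'
#' @param hapA,hapB 0/1 haplotype matrices of the two populations (same SNP
#'   columns).
#' @param core_idx core SNP column.
#' @param positions_bp per-column bp positions.
#' @param trunc combined-sample EHH truncation threshold.
#' @return list `ihh_a`, `ihh_b` (bp-scaled integrals), `edge_truncated`.
#' @export
ihh_pair <- function(hapA, hapB, core_idx, positions_bp, trunc = 0.05) {
  r <- .arm_ihh(hapA, hapB, core_idx, "right", positions_bp, trunc)
  l <- .arm_ihh(hapA, hapB, core_idx, "left", positions_bp, trunc)
  list(ihh_a = r$ihh_a + l$ihh_a,
       ihh_b = r$ihh_b + l$ihh_b,
       edge_truncated = !(r$truncated && l$truncated))
}

#' Cross-population EHH scan
#'
#' Raw XP-EHH at each core SNP is `ln(iHH_A / iHH_B)` with the shared
#' combined-sample truncation of [ihh_pair()]; positive scores indicate
#' longer haplotype homozygosity (recent selection) in population A,
#' negative in population B. Scores are then standardized to mean 0 / sd 1
#' over the scored cores, and the upper and lower `tail` fractions are
#' flagged separately (upper tail = population A, lower = population B).
#'
#' Cores within `edge_margin_bp` of a chromosome end, cores whose combined
#' EHH never decays below the truncation threshold, and cores with a zero
#' iHH in either population are excluded from standardization and flagging.
#'
#' @param panel a phased [haplotype_panel()] with two population labels.
#' @param pops optional character(2): population A and B (order fixes the
#'   sign convention).
#' @param trunc combined EHH truncation threshold (default 0.05).
#' @param tail flagged fraction per tail (default 0.001).
#' @param edge_margin_bp chromosome-end exclusion margin (default 1 Mb).
#' @param ancestral_alleles optional ancestral-allele annotation (any
#'   format). The pooled-EHH form of the statistic is allele-polarity-free,
#'   so the annotation is accepted for interface compatibility but has no
#'   effect; a message notes this.
#' @return data.frame of class `xpehh_scan` with one row per core SNP:
#'   `id`, `chrom`, `bp`, `ihh_a`, `ihh_b`, `raw`, `z`, `excluded`,
#'   `flag_a`, `flag_b`; attributes `thresholds` (upper/lower z cutoffs)
#'   and `pops`.
#' @export
xpehh_scan <- function(panel, pops = NULL, trunc = 0.05, tail = 0.001,
                       edge_margin_bp = 1e6, ancestral_alleles = NULL) {
  if (!is.null(ancestral_alleles))
    message("ancestral-allele annotation ignored: ",
            "the pooled-EHH statistic is polarity-free")
  byp <- split_panel(panel)
  if (is.null(pops)) pops <- names(byp)
  stopifnot(length(pops) == 2, all(pops %in% names(byp)))
  hapA_all <- byp[[pops[1]]]; hapB_all <- byp[[pops[2]]]
  m <- ncol(panel$hap)
  out <- data.frame(id = panel$snps$id, chrom = panel$snps$chrom,
                    bp = panel$snps$bp, ihh_a = NA_real_, ihh_b = NA_real_,
                    raw = NA_real_, z = NA_real_, excluded = TRUE,
                    flag_a = FALSE, flag_b = FALSE, stringsAsFactors = FALSE)
  for (ch in unique(panel$snps$chrom)) {
    cols <- which(panel$snps$chrom == ch)
    bp <- panel$snps$bp[cols]
    hap <- rbind(hapA_all[, cols, drop = FALSE], hapB_all[, cols, drop = FALSE])
    storage.mode(hap) <- "integer"
    res <- .Call(`_flockscan_xpehh_scan_core`, hap, nrow(hapA_all),
                 as.numeric(bp), trunc, as.numeric(edge_margin_bp))
    out$ihh_a[cols] <- ifelse(res[, 3] == 2, NA_real_, res[, 1])
    out$ihh_b[cols] <- ifelse(res[, 3] == 2, NA_real_, res[, 2])
    ok <- res[, 3] == 0 & res[, 1] > 0 & res[, 2] > 0
    ok[is.na(ok)] <- FALSE
    out$raw[cols[ok]] <- log(res[ok, 1] / res[ok, 2])
    out$excluded[cols[ok]] <- FALSE
  }
  sc <- standardize_and_call(out$raw[!out$excluded], tail)
  out$z[!out$excluded] <- sc$z
  out$flag_a[!out$excluded] <- sc$flag_upper
  out$flag_b[!out$excluded] <- sc$flag_lower
  attr(out, "thresholds") <- sc$thresholds
  attr(out, "pops") <- pops
  class(out) <- c("xpehh_scan", class(out))
  out
}

#' Standardize scores and flag the two tails
#'
#' `z = (x - mean) / sd`; the upper and lower `tail` fractions are flagged
#' separately against the empirical `1 - tail` and `tail` quantiles (strict
#' inequality).
#'
#' @param raw finite raw scores.
#' @param tail per-tail fraction (default 0.001).
#' @return list `z`, `flag_upper`, `flag_lower`, `thresholds` (named upper/
#'   lower, on the z scale).
#' @export
standardize_and_call <- function(raw, tail = 0.001) {
  if (length(raw) < 1000)
    warning("fewer than 1000 scores: ", tail, " tail thresholds are unstable")
  s <- stats::sd(raw)
  z <- if (is.na(s) || s == 0) rep(0, length(raw)) else (raw - mean(raw)) / s
  up <- stats::quantile(z, 1 - tail, names = FALSE)
  lo <- stats::quantile(z, tail, names = FALSE)
  list(z = z, flag_upper = z > up, flag_lower = z < lo,
       thresholds = c(upper = up, lower = lo))
}

#' @export
print.xpehh_scan <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat("<xpehh_scan> ", nrow(x), " cores (", sum(!x$excluded), " scored), pops ",
      paste(attr(x, "pops"), collapse = " vs "), "\n", sep = "")
  cat(sprintf("  z thresholds: %.3f < z < %.3f; %d upper, %d lower flags\n",
              th["lower"], th["upper"], sum(x$flag_a), sum(x$flag_b)))
  invisible(x)
}
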