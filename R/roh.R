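#' ROH detection parameters
#'
#' Segment-level criteria for a run of homozygosity: at most `max_missing`
#' missing and `max_het` heterozygous genotypes inside the run, at least
#' `min_snps` SNPs, an overall density of at least one SNP per
#' `min_density_bp` bp (evaluated on the whole segment, PLINK-style:
#' `length_bp / n_snps <= min_density_bp`), no gap between consecutive SNPs
#' exceeding `max_gap_bp`, and a minimum physical length `min_length_bp`.
#'
#' @param max_missing allowed missing genotypes inside a run (default 2).
#' @param max_het allowed heterozygous genotypes inside a run (default 1).
#' @param min_snps minimum SNP count (default 40; see [min_snps_lencz()]).
#' @param min_density_bp maximum bp per SNP (default 100 kb).
#' @param max_gap_bp maximum gap between consecutive SNPs (default 250 kb).
#' @param min_length_bp minimum segment length (default 1 Mb, the lower edge
#'   of the smallest reported length class).
#' @return An object of class `roh_params`.
#' @export
roh_params <- function(max_missing = 2L, max_het = 1L, min_snps = 40L,
                       min_density_bp = 1e5, max_gap_bp = 2.5e5,
                       min_length_bp = 1e6) {
  stopifnot(max_missing >= 0, max_het >= 0, min_snps >= 1,
            min_density_bp >= 0, max_gap_bp >= 0, min_length_bp >= 0)
  structure(list(max_missing = as.integer(max_missing),
                 max_het = as.integer(max_het),
                 min_snps = as.integer(min_snps),
                 min_density_bp = min_density_bp,
                 max_gap_bp = max_gap_bp,
                 min_length_bp = min_length_bp),
            class = "roh_params")
}

#' Minimum informative SNP count for ROH calling
#'
#' The false-positive-controlling minimum number of SNPs in a run:
#' `l = log(alpha / (n_s * n_i)) / log(1 - mean_het)`.
#'
#' @param n_s number of genotyped SNPs per individual.
#' @param n_i number of individuals.
#' @param alpha tolerated fraction of false-positive ROH (default 0.05).
#' @param mean_het mean SNP heterozygosity across SNPs, in (0, 1).
#' @return list with `raw` (the real-valued l) and `min_snps` (its ceiling).
#' @export
min_snps_lencz <- function(n_s, n_i, alpha = 0.05, mean_het) {
  stopifnot(n_s >= 1, n_i >= 1, alpha > 0, alpha <= 1)
  if (mean_het <= 0 || mean_het >= 1)
    stop("mean_het must lie strictly between 0 and 1")
  raw <- log(alpha / (n_s * n_i)) / log(1 - mean_het)
  list(raw = raw, min_snps = ceiling(raw))
}

# qualifying check for dosage vector d (0/1/2/NA) over indices i..j with bp
.run_ok <- function(d, bp, i, j, par) {
  n <- j - i + 1L
  if (n < par$min_snps) return(FALSE)
  seg <- d[i:j]
  if (sum(seg == 1L, na.rm = TRUE) > par$max_het) return(FALSE)
  if (sum(is.na(seg)) > par$max_missing) return(FALSE)
  if (n > 1L && max(diff(bp[i:j])) > par$max_gap_bp) return(FALSE)
  len <- bp[j] - bp[i] + 1
  if (len < par$min_length_bp) return(FALSE)
  if (len / n > par$min_density_bp) return(FALSE)
  TRUE
}

# maximal non-overlapping qualifying runs for a single individual/chromosome
.scan_chrom <- function(d, bp, par) {
  m <- length(d)
  out <- NULL
  i <- 1L
  het <- cumsum(ifelse(is.na(d), 0L, d == 1L))
  mis <- cumsum(is.na(d))
  gap_brk <- c(which(diff(bp) > par$max_gap_bp), m)  # last index before a break
  hom <- !is.na(d) & d != 1L   # runs start and end on homozygous calls
  while (i <= m) {
    if (!hom[i]) { i <- i + 1L; next }
    # furthest end not violating the monotone criteria (het, missing, gap)
    lim_gap <- gap_brk[gap_brk >= i][1]
    h0 <- if (i > 1L) het[i - 1L] else 0L
    m0 <- if (i > 1L) mis[i - 1L] else 0L
    lim <- lim_gap
    over <- which(het[i:lim] - h0 > par$max_het | mis[i:lim] - m0 > par$max_missing)
    if (length(over)) lim <- i + over[1] - 2L
    # among ends i..lim take the largest j satisfying the remaining criteria
    best <- NA_integer_
    if (lim - i + 1L >= par$min_snps) {
      js <- seq(i + par$min_snps - 1L, lim)
      len <- bp[js] - bp[i] + 1
      nn <- js - i + 1L
      ok <- hom[js] & len >= par$min_length_bp & len / nn <= par$min_density_bp
      if (any(ok)) best <- js[max(which(ok))]
    }
    if (is.na(best)) {
      i <- i + 1L
    } else {
      out <- rbind(out, c(i, best))
      i <- best + 1L
    }
  }
  out
}

#' Detect runs of homozygosity
#'
#' Scans each individual and chromosome for maximal segments satisfying
#' every criterion in `params`; maximality means that extending either end
#' by one SNP violates at least one criterion, and reported segments within
#' an individual/chromosome never overlap (overlapping candidates are
#' resolved left-to-right, preferring the longest run from the leftmost
#' qualifying start). A segment's first and last SNP must be homozygous
#' non-missing calls — the heterozygote/missing budgets apply to its
#' interior — so runs are never padded with flanking heterozygotes.
#'
#' @param gm a [genotype_matrix()].
#' @param params a [roh_params()].
#' @return data.frame with columns `iid`, `pop`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`; zero rows when nothing qualifies.
#' @export
detect_roh <- function(gm, params = roh_params()) {
  res <- list()
  chroms <- unique(gm$snps$chrom)
  for (ch in chroms) {
    cols <- which(gm$snps$chrom == ch)
    bp <- gm$snps$bp[cols]
    for (k in seq_len(n_ind(gm))) {
      d <- gm$dosage[k, cols]
      runs <- .scan_chrom(d, bp, params)
      if (!is.null(runs)) {
        res[[length(res) + 1L]] <- data.frame(
          iid = gm$samples$iid[k], pop = gm$samples$pop[k], chrom = ch,
          start_bp = bp[runs[, 1]], end_bp = bp[runs[, 2]],
          n_snps = runs[, 2] - runs[, 1] + 1L,
          length_bp = bp[runs[, 2]] - bp[runs[, 1]] + 1,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(iid = character(), pop = character(), chrom = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_bp = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' ROH-based genomic inbreeding coefficient
#'
#' `F_ROH = sum(ROH lengths) / L_auto` per individual; individuals without
#' any ROH get 0.
#'
#' @param segments data.frame from [detect_roh()].
#' @param gm the [genotype_matrix()] the segments came from (supplies the
#'   individual list; individuals without segments are included with 0).
#' @param L_auto_bp total autosomal length covered by SNPs, in bp. By
#'   default, the summed per-chromosome span from first to last mapped SNP.
#' @return data.frame with `iid`, `pop`, `l_roh_bp`, `froh`.
#' @export
froh <- function(segments, gm, L_auto_bp = NULL) {
  if (is.null(L_auto_bp)) {
    sp <- tapply(gm$snps$bp, gm$snps$chrom, function(b) max(b) - min(b) + 1)
    L_auto_bp <- sum(sp)
  }
  stopifnot(L_auto_bp > 0)
  tot <- tapply(segments$length_bp, segments$iid, sum)
  l <- as.numeric(tot[match(gm$samples$iid, names(tot))])
  l[is.na(l)] <- 0
  data.frame(iid = gm$samples$iid, pop = gm$samples$pop,
             l_roh_bp = l, froh = l / L_auto_bp, stringsAsFactors = FALSE)
}

#' Summarise detected ROH
#'
#' Per-individual counts and total lengths; the per-breed mean sum of ROH
#' per length class (classes `[1,5)`, `[5,10)`, `[10,15)`, `[15,20)`,
#' `[20,Inf)` Mb — each individual's segment lengths are summed within class,
#' then averaged over the individuals of each population); per-chromosome
#' segment counts and percent of the chromosome covered by ROH (chromosome
#' length = span from first to last mapped SNP).
#'
#' @param segments data.frame from [detect_roh()].
#' @param gm the source [genotype_matrix()].
#' @return list of data.frames `per_individual`, `class_mean_sum`,
#'   `per_chromosome`, of class `roh_summary`.
#' @export
summarize_roh <- function(segments, gm) {
  iids <- gm$samples$iid
  pops <- gm$samples$pop
  cnt <- table(factor(segments$iid, levels = iids))
  tot <- tapply(segments$length_bp, factor(segments$iid, levels = iids), sum)
  tot[is.na(tot)] <- 0
  per_ind <- data.frame(iid = iids, pop = pops, n_roh = as.integer(cnt),
                        total_length_bp = as.numeric(tot),
                        stringsAsFactors = FALSE)

  breaks <- c(1, 5, 10, 15, 20, Inf)
  labels <- c("1-5Mb", "5-10Mb", "10-15Mb", "15-20Mb", ">=20Mb")
  cls <- cut(segments$length_bp / 1e6, breaks = breaks, labels = labels,
             right = FALSE)
  class_rows <- list()
  for (pp in unique(pops)) {
    pids <- iids[pops == pp]
    for (ci in seq_along(labels)) {
      sel <- segments$pop == pp & !is.na(cls) & cls == labels[ci]
      sums <- tapply(segments$length_bp[sel],
                     factor(segments$iid[sel], levels = pids), sum)
      sums[is.na(sums)] <- 0
      class_rows[[length(class_rows) + 1L]] <-
        data.frame(pop = pp, class = labels[ci],
                   mean_sum_mb = mean(sums) / 1e6, stringsAsFactors = FALSE)
    }
  }
  class_mean <- do.call(rbind, class_rows)

  chroms <- sort(unique(gm$snps$chrom))
  chrom_rows <- lapply(chroms, function(ch) {
    bp <- gm$snps$bp[gm$snps$chrom == ch]
    clen <- max(bp) - min(bp) + 1
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    # mean per-individual coverage fraction over individuals in gm
    cov_by_ind <- tapply(seg$length_bp, factor(seg$iid, levels = iids), sum)
    cov_by_ind[is.na(cov_by_ind)] <- 0
    data.frame(chrom = ch, n_roh = nrow(seg),
               pct_covered = 100 * mean(cov_by_ind) / clen,
               stringsAsFactors = FALSE)
  })
  per_chrom <- do.call(rbind, chrom_rows)

  structure(list(per_individual = per_ind, class_mean_sum = class_mean,
                 per_chromosome = per_chrom), class = "roh_summary")
}

#' @export
print.roh_summary <- function(x, ...) {
  cat("<roh_summary>\n per-individual totals:\n")
  print(utils::head(x$per_individual))
  cat(" mean sum per length class (Mb):\n")
  print(x$class_mean_sum)
  invisible(x)
}

#' Write a segment table as TSV
#' @param segments data.frame from [detect_roh()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_roh_segments <- function(segments, path) {
  out <- segments
  out$length_mb <- out$length_bp / 1e6
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
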