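#' Construct a genotype matrix
#'
#' The central container of the package: a diploid dosage table (individuals
#' in rows, SNPs in columns) together with its SNP map and per-individual
#' population labels. Dosages count copies of `allele_b` (0, 1, 2, or `NA`
#' for missing). SNPs are stored sorted by (chromosome, position).
#'
#' @param dosage integer matrix, `n_ind x n_snp`, values in `{0, 1, 2, NA}`.
#' @param snps data.frame with columns `id`, `chrom` (integer code; 1-26
#'   autosomes, 27 = X by the usual ovine convention, 0 = unplaced), `bp`
#'   (1-based physical position), `allele_a`, `allele_b` (single characters;
#'   `allele_b` is the dosage-counted allele).
#' @param samples data.frame with columns `iid` (unique individual id) and
#'   `pop` (non-empty population label).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  gm <- structure(list(dosage = dosage, snps = snps, samples = samples),
                  class = "genotype_matrix")
  gm <- sort_snps(gm)
  validate_genotype_matrix(gm)
  gm
}

sort_snps <- function(gm) {
  ord <- order(gm$snps$chrom, gm$snps$bp)
  if (is.unsorted(ord)) {
    gm$snps <- gm$snps[ord, , drop = FALSE]
    gm$dosage <- gm$dosage[, ord, drop = FALSE]
    rownames(gm$snps) <- NULL
  }
  gm
}

validate_genotype_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  if (nrow(d) != nrow(gm$samples))
    stop("dosage rows (", nrow(d), ") != number of samples (", nrow(gm$samples), ")")
  if (ncol(d) != nrow(gm$snps))
    stop("dosage columns (", ncol(d), ") != number of SNPs (", nrow(gm$snps), ")")
  if (anyDuplicated(gm$snps$id)) stop("duplicate SNP ids")
  if (anyDuplicated(gm$samples$iid)) stop("duplicate individual ids")
  if (any(!nzchar(gm$samples$pop))) stop("empty population label")
  bad <- d[!is.na(d)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  if (any(gm$snps$bp < 1L)) stop("bp positions must be >= 1")
  # strictly increasing bp within chromosome
  for (ch in unique(gm$snps$chrom)) {
    bp <- gm$snps$bp[gm$snps$chrom == ch]
    if (any(diff(bp) <= 0))
      stop("bp not strictly increasing on chromosome ", ch)
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " individuals x ",
      ncol(x$dosage), " SNPs\n", sep = "")
  tb <- table(x$samples$pop)
  cat("  populations: ",
      paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n", sep = "")
  cat("  chromosomes: ", paste(sort(unique(x$snps$chrom)), collapse = " "),
      "\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missingness: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / SNPs in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_ind <- function(gm) nrow(gm$dosage)

#' @rdname n_ind
#' @export
n_snp <- function(gm) ncol(gm$dosage)

#' Subset a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @param ind logical/integer index over individuals (default all).
#' @param snp logical/integer index over SNPs (default all).
#' @return A `genotype_matrix` restricted to the selection; individual order
#'   is preserved, SNP order stays sorted.
#' @export
subset_gm <- function(gm, ind = NULL, snp = NULL) {
  if (!is.null(ind)) {
    gm$dosage <- gm$dosage[ind, , drop = FALSE]
    gm$samples <- gm$samples[ind, , drop = FALSE]
    rownames(gm$samples) <- NULL
  }
  if (!is.null(snp)) {
    gm$dosage <- gm$dosage[, snp, drop = FALSE]
    gm$snps <- gm$snps[snp, , drop = FALSE]
    rownames(gm$snps) <- NULL
  }
  gm
}

#' Per-SNP allele frequency of allele_b
#'
#' @param gm a `genotype_matrix`.
#' @param pop optional population label; default pools all individuals.
#' @return numeric vector of allele-b frequencies (NaN where all missing).
#' @export
allele_freq <- function(gm, pop = NULL) {
  d <- gm$dosage
  if (!is.null(pop)) d <- d[gm$samples$pop == pop, , drop = FALSE]
  colMeans(d, na.rm = TRUE) / 2
}

#' Construct a phased haplotype panel
#'
#' Binary haplotypes (0 = allele_a, 1 = allele_b), two consecutive rows per
#' individual, in the same individual and SNP order as the companion
#' genotype matrix. Rows `2k-1` and `2k` belong to individual `k` and must sum,
#' SNP-wise, to that individual's dosage wherever the dosage is non-missing.
#'
#' @param hap integer matrix `2*n_ind x n_snp` of 0/1.
#' @param gm the companion `genotype_matrix`.
#' @return An object of class `haplotype_panel` (fields `hap`, `snps`,
#'   `samples`).
#' @export
haplotype_panel <- function(hap, gm) {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  if (nrow(hap) != 2L * n_ind(gm))
    stop("haplotype rows (", nrow(hap), ") != 2 * individuals (", 2L * n_ind(gm), ")")
  if (ncol(hap) != n_snp(gm))
    stop("haplotype columns != number of SNPs")
  if (any(hap != 0L & hap != 1L)) stop("haplotype entries must be 0/1")
  dos <- hap[seq(1L, nrow(hap), by = 2L), , drop = FALSE] +
         hap[seq(2L, nrow(hap), by = 2L), , drop = FALSE]
  obs <- !is.na(gm$dosage)
  if (any(dos[obs] != gm$dosage[obs]))
    stop("haplotype pair sums disagree with dosage table")
  structure(list(hap = hap, snps = gm$snps, samples = gm$samples),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$hap), " haplotypes x ", ncol(x$hap),
      " SNPs (", nrow(x$samples), " individuals)\n", sep = "")
  invisible(x)
}

#' Split a haplotype panel by population
#'
#' @param panel a `haplotype_panel`.
#' @return Named list of 0/1 matrices, one per population label, rows =
#'   haplotypes of that population's individuals.
#' @export
split_panel <- function(panel) {
  pops <- unique(panel$samples$pop)
  out <- lapply(pops, function(p) {
    k <- which(panel$samples$pop == p)
    rows <- as.vector(rbind(2L * k - 1L, 2L * k))
    panel$hap[rows, , drop = FALSE]
  })
  names(out) <- pops
  out
}
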