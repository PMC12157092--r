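# fixture builders ----------------------------------------------------------

make_gm <- function(dosage, chrom = NULL, bp = NULL, pop = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(bp)) bp <- unlist(lapply(split(seq_len(m), chrom), seq_along)) * 1e5
  if (is.null(pop)) pop <- rep(c("A", "B"), length.out = n)
  genotype_matrix(dosage,
                  snps = data.frame(id = sprintf("s%d", seq_len(m)),
                                    chrom = as.integer(chrom),
                                    bp = bp, allele_a = rep("A", m),
                                    allele_b = rep("B", m),
                                    stringsAsFactors = FALSE),
                  samples = data.frame(iid = sprintf("i%03d", seq_len(n)),
                                       pop = pop, stringsAsFactors = FALSE))
}

random_gm <- function(n = 10, m = 20, miss = 0.05, n_chrom = 1, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  if (miss > 0) d[runif(n * m) < miss] <- NA
  chrom <- sort(rep_len(seq_len(n_chrom), m))
  bp <- unlist(lapply(split(seq_len(m), chrom), function(i)
    sort(sample.int(5e7, length(i)))))
  make_gm(d, chrom = chrom, bp = bp)
}

random_panel <- function(n_ind = 10, m = 30, seed = 1, pop = NULL) {
  set.seed(seed)
  hap <- matrix(rbinom(2 * n_ind * m, 1, 0.5), 2 * n_ind, m)
  dos <- hap[seq(1, 2 * n_ind, 2), ] + hap[seq(2, 2 * n_ind, 2), ]
  gm <- make_gm(dos, bp = sort(sample.int(5e7, m)), pop = pop)
  list(gm = gm, panel = haplotype_panel(hap, gm))
}

# small neutral two-population simulation used by several scan tests
quick_sim <- function(seed, m = 300, n_chrom = 1, split_g = 30, N = 60,
                      burn_in = 40, samples = c(A = 20, B = 18),
                      sweep = NULL, inbreeding = NULL, track_ibd = FALSE,
                      chrom_len = 2e7) {
  cfg <- sim_config(n_chrom = n_chrom, chrom_length_bp = chrom_len,
                    n_snp_per_chrom = m, ancestral_ne = N, burn_in = burn_in,
                    ne_schedule = list(A = cbind(span = split_g, N = N),
                                       B = cbind(span = split_g, N = N)),
                    sample_size = samples, sweep = sweep,
                    inbreeding = inbreeding, track_ibd = track_ibd,
                    seed = seed)
  sim_population(cfg)
}

# independent oracles --------------------------------------------------------

# exhaustive ROH oracle: enumerate every sub-interval, keep qualifying ones,
# reduce to maximal non-overlapping segments (smallest start, then largest
# end, discard overlaps, recurse)
roh_oracle <- function(d, bp, par) {
  m <- length(d)
  hom <- !is.na(d) & d != 1L
  qual <- list()
  for (i in seq_len(m)) {
    for (j in i:m) {
      if (!hom[i] || !hom[j]) next
      n <- j - i + 1
      if (n < par$min_snps) next
      seg <- d[i:j]
      if (sum(seg == 1L, na.rm = TRUE) > par$max_het) next
      if (sum(is.na(seg)) > par$max_missing) next
      if (n > 1 && max(diff(bp[i:j])) > par$max_gap_bp) next
      len <- bp[j] - bp[i] + 1
      if (len < par$min_length_bp) next
      if (len / n > par$min_density_bp) next
      qual[[length(qual) + 1]] <- c(i, j)
    }
  }
  if (!length(qual)) return(matrix(integer(), 0, 2))
  q <- do.call(rbind, qual)
  out <- NULL
  repeat {
    if (!nrow(q)) break
    o <- order(q[, 1], -q[, 2])
    top <- q[o[1], ]
    out <- rbind(out, top)
    q <- q[q[, 1] > top[2], , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# Weir & Cockerham theta via the allele-indicator nested ANOVA mean squares
wc_oracle <- function(d1, d2) {
  pops <- list(d1[!is.na(d1)], d2[!is.na(d2)])
  ni <- vapply(pops, length, 0)
  if (any(ni < 2)) return(NA_real_)
  pi <- vapply(pops, function(x) mean(x) / 2, 0)
  r <- 2
  nbar <- mean(ni)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  pw <- sum(ni * pi) / sum(ni)
  SSP <- sum(2 * ni * (pi - pw)^2)
  SSI <- sum(vapply(seq_len(r), function(k)
    sum(2 * (pops[[k]] / 2 - pi[k])^2), 0))
  SSG <- sum(vapply(pops, function(x) sum(x == 1) / 2, 0))
  MSP <- SSP / (r - 1)
  MSI <- SSI / (sum(ni) - r)
  MSG <- SSG / sum(ni)
  s2G <- MSG
  s2I <- (MSI - MSG) / 2
  s2P <- (MSP - MSI) / (2 * nc)
  tot <- s2P + s2I + s2G
  if (tot == 0) return(NA_real_)
  s2P / tot
}

# EHH oracle: group haplotypes by the string of alleles from the core
# through SNP j (inclusive) and apply the pair-count formula
ehh_oracle <- function(hap, core, j) {
  lo <- min(core, j); hi <- max(core, j)
  key <- apply(hap[, lo:hi, drop = FALSE], 1, paste, collapse = "")
  sz <- table(key)
  n <- nrow(hap)
  sum(sz * (sz - 1) / 2) / (n * (n - 1) / 2)
}

# Benjamini-Hochberg from first principles
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# exact HWE p-values precomputed with rational arithmetic (Python fractions):
# full enumeration of heterozygote counts conditional on allele counts,
# summing configurations with probability <= the observed one
hwe_rational_cases <- list(
  list(c(0L, 50L, 0L), 1.241246728270939e-14),
  list(c(25L, 0L, 25L), 1.2529380692380692e-15),
  list(c(5L, 10L, 5L), 1.0),
  list(c(10L, 21L, 10L), 1.0),
  list(c(3L, 1L, 40L), 0.00017106967423446322),
  list(c(0L, 3L, 60L), 1.0),
  list(c(12L, 40L, 48L), 0.48945800737807493),
  list(c(30L, 40L, 30L), 0.04685521181344839),
  list(c(1L, 0L, 1L), 0.3333333333333333),
  list(c(7L, 2L, 11L), 0.00038681618214432453),
  list(c(2L, 30L, 2L), 1.4763345361214615e-05),
  list(c(45L, 10L, 45L), 2.1260317926714968e-17)
)

# independent R enumeration of the same conditional distribution, written
# against the closed-form single-configuration probability
hwe_enum_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  prob_one <- function(h) {
    nAA_ <- (nA - h) / 2
    naa_ <- n - nAA_ - h
    exp(lfactorial(n) - lfactorial(nAA_) - lfactorial(h) - lfactorial(naa_) +
          h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
          lfactorial(2 * n))
  }
  rare <- min(nA, 2 * n - nA)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, prob_one, 0)
  pobs <- pr[match(nAa, hets)]
  sum(pr[pr <= pobs * (1 + 1e-9)])
}
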