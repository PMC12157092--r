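test_that("minimum-SNP formula evaluates, bounds and degenerates correctly", {
  l <- min_snps_lencz(44152, 41, 0.05, 0.35)
  expect_equal(l$raw, log(0.05 / (44152 * 41)) / log(1 - 0.35), tolerance = 1e-12)
  expect_equal(round(l$raw, 1), 40.4)
  expect_equal(l$min_snps, 41)
  # l decreases as heterozygosity rises
  raws <- sapply(c(0.2, 0.3, 0.4, 0.5), function(h)
    min_snps_lencz(44152, 41, 0.05, h)$raw)
  expect_true(all(diff(raws) < 0))
  # alpha = 1, n_s = n_i = 1 -> numerator log(1) = 0
  expect_equal(min_snps_lencz(1, 1, 1, 0.3)$raw, 0)
  expect_error(min_snps_lencz(10, 10, 0.05, 0), "mean_het")
})

test_that("constructed homozygous stretch yields exactly one segment", {
  # 45 homozygous SNPs spaced 100 kb (span 4.4 Mb) flanked by heterozygotes
  d <- c(1L, rep(0L, 45), 1L)
  bp <- seq(1e5, by = 1e5, length.out = 47)
  gm <- make_gm(matrix(d, 1), bp = bp, pop = "A")
  seg <- detect_roh(gm, roh_params())
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 45L)
  expect_equal(seg$start_bp, 2e5)
  expect_equal(seg$end_bp, 46e5)
  # all-heterozygous individual: nothing
  gm2 <- make_gm(matrix(1L, 1, 50), bp = seq(1e5, by = 1e5, length.out = 50))
  expect_equal(nrow(detect_roh(gm2, roh_params())), 0L)
})

test_that("detector equals the exhaustive sub-interval oracle on random fixtures", {
  par <- roh_params(min_snps = 8L, min_density_bp = 2e5, max_gap_bp = 4e5,
                    min_length_bp = 5e5)
  for (seed in 1:25) {
    set.seed(seed)
    m <- sample(30:80, 1)
    d <- sample(c(0L, 1L, 2L, NA), m, replace = TRUE,
                prob = c(0.55, 0.12, 0.3, 0.03))
    bp <- sort(sample.int(1.2e7, m))
    gm <- make_gm(matrix(d, 1), bp = bp, pop = "A")
    got <- detect_roh(gm, par)
    want <- roh_oracle(d, bp, par)
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    if (nrow(want)) {
      expect_equal(got$start_bp, bp[want[, 1]], info = paste("seed", seed))
      expect_equal(got$end_bp, bp[want[, 2]], info = paste("seed", seed))
    }
  }
})

test_that("relaxing the heterozygote budget never shrinks total ROH length", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- sample(c(0L, 1L, 2L), 120, replace = TRUE, prob = c(0.5, 0.15, 0.35))
    bp <- sort(sample.int(2e7, 120))
    gm <- make_gm(matrix(d, 1), bp = bp, pop = "A")
    strict <- detect_roh(gm, roh_params(min_snps = 10, max_het = 1,
                                        min_density_bp = 3e5, max_gap_bp = 8e5))
    loose <- detect_roh(gm, roh_params(min_snps = 10, max_het = 1e6,
                                       min_density_bp = 3e5, max_gap_bp = 8e5))
    expect_gte(sum(loose$length_bp), sum(strict$length_bp))
  }
})

test_that("F_ROH is the forced ratio and invariant to irrelevant SNPs", {
  gm <- make_gm(matrix(0L, 2, 4), bp = c(1, 2, 3, 4) * 1e6, pop = c("A", "A"))
  seg <- data.frame(iid = "i001", pop = "A", chrom = 1L, start_bp = 1,
                    end_bp = 24.63e6, n_snps = 100L, length_bp = 24.63e6)
  f <- froh(seg, gm, L_auto_bp = 2.463e9)
  expect_equal(f$froh, c(0.01, 0))  # second individual: no ROH -> 0
  # invariance to chromosome ordering of the segment table
  seg2 <- rbind(seg, transform(seg, chrom = 2L, length_bp = 1e6))
  expect_equal(froh(seg2[2:1, ], gm, 2.463e9)$froh,
               froh(seg2, gm, 2.463e9)$froh)
})

test_that("summary bins lengths into the five classes and partitions totals", {
  segs <- data.frame(iid = rep("i001", 3), pop = "A", chrom = 1L,
                     start_bp = c(1, 1, 1) * 1e6,
                     end_bp = c(7, 13, 30) * 1e6,
                     n_snps = 50L,
                     length_bp = c(6, 12, 29) * 1e6)
  gm <- make_gm(matrix(0L, 1, 3), bp = c(1e6, 2e7, 4e7), pop = "A")
  s <- summarize_roh(segs, gm)
  cm <- s$class_mean_sum
  expect_equal(cm$mean_sum_mb[cm$class == "5-10Mb"], 6)
  expect_equal(cm$mean_sum_mb[cm$class == "10-15Mb"], 12)
  expect_equal(cm$mean_sum_mb[cm$class == ">=20Mb"], 29)
  expect_equal(cm$mean_sum_mb[cm$class == "1-5Mb"], 0)
  # class sums partition the per-individual total
  expect_equal(sum(cm$mean_sum_mb) * 1e6, s$per_individual$total_length_bp[1])
  expect_equal(s$per_chromosome$n_roh, 3L)
})

test_that("simulated full-sib inbreeding raises autozygosity and F_ROH", {
  inbred <- quick_sim(seed = 31, m = 500, N = 50, burn_in = 20, split_g = 12,
                      samples = c(A = 25, B = 10), track_ibd = TRUE,
                      inbreeding = list(pop = "A", fraction = 1, generations = 4))
  control <- quick_sim(seed = 31, m = 500, N = 50, burn_in = 20, split_g = 12,
                       samples = c(A = 25, B = 10), track_ibd = TRUE)
  az_i <- inbred$truth$autozygosity
  az_c <- control$truth$autozygosity
  expect_gt(mean(az_i$autozygosity[az_i$pop == "A"]),
            mean(az_c$autozygosity[az_c$pop == "A"]))
  par <- roh_params(min_snps = 15, min_density_bp = 2e5, max_gap_bp = 1e6)
  f_i <- froh(detect_roh(inbred$gm, par), inbred$gm)
  f_c <- froh(detect_roh(control$gm, par), control$gm)
  expect_gt(mean(f_i$froh[f_i$pop == "A"]), mean(f_c$froh[f_c$pop == "A"]))
})
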