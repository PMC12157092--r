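test_that("call-rate filter removes at the 95% boundary, individuals first", {
  # 20 SNPs: individual 1 misses 2 (90%), individual 2 misses 1 (95%)
  d <- matrix(1L, 4, 20)
  d[1, 1:2] <- NA; d[2, 3] <- NA
  gm <- make_gm(d)
  r <- filter_call_rate(gm, 0.95)
  expect_equal(r$gm$samples$iid, gm$samples$iid[-1])
  expect_equal(r$report$ind_removed, 1L)
  # complete matrix unchanged
  r2 <- filter_call_rate(make_gm(matrix(2L, 3, 4)), 0.95)
  expect_equal(r2$report$ind_removed + r2$report$snp_removed, 0L)
})

test_that("call-rate filter matches a brute-force recount on a random fixture", {
  gm <- random_gm(n = 10, m = 20, miss = 0.08, seed = 42)
  r <- filter_call_rate(gm, 0.95)
  keep_i <- rowMeans(!is.na(gm$dosage)) >= 0.95
  d2 <- gm$dosage[keep_i, , drop = FALSE]
  keep_s <- colMeans(!is.na(d2)) >= 0.95
  expect_equal(unname(r$gm$dosage), unname(d2[, keep_s, drop = FALSE]))
})

test_that("MAF filter is strict and pooled across populations", {
  # 25 individuals: SNP1 monomorphic, SNP2 MAF exactly 0.02, SNP3 common
  d <- cbind(rep(0L, 25), c(1L, rep(0L, 24)), rep(1L, 25))
  gm <- make_gm(d)
  r <- filter_maf(gm, 0.02)
  expect_equal(r$gm$snps$id, c("s2", "s3"))  # exact threshold retained
  expect_equal(r$report$snp_removed, 1L)
  # brute-force allele counting on a random fixture
  gm2 <- random_gm(n = 12, m = 30, miss = 0.1, seed = 9)
  r2 <- filter_maf(gm2, 0.1)
  p <- colMeans(gm2$dosage, na.rm = TRUE) / 2
  expect_equal(r2$gm$snps$id, gm2$snps$id[pmin(p, 1 - p) >= 0.1])
})

test_that("exact HWE test: modal configuration, symmetry, oracle equality", {
  # the modal heterozygote count has maximal probability -> p = 1
  expect_equal(hwe_exact_test(5, 10, 5), 1)
  # label symmetry AA <-> aa
  for (cs in list(c(3, 7, 12), c(0, 5, 20))) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_exact_test(cs[3], cs[2], cs[1]))
  }
  # frozen exact-rational values
  for (case in hwe_rational_cases) {
    expect_equal(hwe_exact_test(case[[1]][1], case[[1]][2], case[[1]][3]),
                 case[[2]], tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(0, 0, 0), "undefined")
})

test_that("HWE filter removes a SNP failing in any single population", {
  # SNP1 wildly out of HWE in pop B only; SNP2 fine everywhere
  set.seed(1)
  dA <- cbind(rbinom(50, 2, 0.5), rbinom(50, 2, 0.5))
  dB <- cbind(c(rep(0L, 25), rep(2L, 25)), rbinom(50, 2, 0.5))
  gm <- make_gm(rbind(dA, dB), pop = rep(c("A", "B"), each = 50))
  r <- filter_hwe(gm, alpha = 1e-6)
  expect_false("s1" %in% r$gm$snps$id)
  expect_true("s2" %in% r$gm$snps$id)
  # alpha = 0 removes nothing
  r0 <- filter_hwe(gm, alpha = 0)
  expect_equal(r0$report$snp_removed, 0L)
  # matches a per-population oracle on a random fixture
  gm2 <- random_gm(n = 40, m = 25, miss = 0, seed = 5)
  r2 <- filter_hwe(gm2, alpha = 0.05)
  drop <- sapply(seq_len(n_snp(gm2)), function(j) {
    any(sapply(c("A", "B"), function(pp) {
      dd <- gm2$dosage[gm2$samples$pop == pp, j]
      hwe_enum_oracle(sum(dd == 0), sum(dd == 1), sum(dd == 2)) < 0.05
    }))
  })
  expect_equal(r2$gm$snps$id, gm2$snps$id[!drop])
})

test_that("unplaced and non-autosomal SNPs are dropped per mode", {
  gm <- make_gm(matrix(1L, 3, 4), chrom = c(0L, 1L, 26L, 27L),
                bp = c(100, 100, 100, 100))
  r <- drop_unplaced(gm, autosomes_only = TRUE)
  expect_equal(r$gm$snps$chrom, c(1L, 26L))
  r2 <- drop_unplaced(gm, autosomes_only = FALSE)
  expect_equal(r2$gm$snps$chrom, c(1L, 26L, 27L))
})

test_that("naive imputation is seeded, frequency-preserving and idempotent", {
  gm <- random_gm(n = 200, m = 50, miss = 0.2, seed = 11)
  i1 <- impute_naive(gm, seed = 3)
  i2 <- impute_naive(gm, seed = 3)
  expect_identical(i1$dosage, i2$dosage)
  expect_false(anyNA(i1$dosage))
  # no-missing input unchanged
  expect_identical(impute_naive(i1, seed = 99)$dosage, i1$dosage)
  # imputed allele frequency within 3 binomial SEs of the source frequency
  for (j in seq_len(25)) {
    obs <- !is.na(gm$dosage[, j])
    if (sum(!obs) < 10) next
    p_src <- mean(gm$dosage[obs, j]) / 2
    p_imp <- mean(i1$dosage[!obs, j]) / 2
    se <- sqrt(p_src * (1 - p_src) / (2 * sum(!obs)))
    expect_lt(abs(p_imp - p_src), 3 * se + 1e-9)
  }
})

test_that("the QC cascade is ordered, accountable and idempotent", {
  gm <- random_gm(n = 30, m = 60, miss = 0.06, n_chrom = 2, seed = 21)
  res <- run_qc(gm, call_rate = 0.95, min_maf = 0.1, hwe_alpha = 1e-3,
                seed = 2)
  expect_equal(res$report$stage,
               c("call_rate", "unplaced_nonautosomal", "maf", "hwe"))
  expect_equal(sum(res$report$ind_removed),
               n_ind(gm) - n_ind(res$gm))
  expect_equal(sum(res$report$snp_removed),
               n_snp(gm) - n_snp(res$gm))
  # each filter applied twice equals once
  f1 <- filter_maf(gm, 0.1)$gm
  expect_equal(filter_maf(f1, 0.1)$gm$snps$id, f1$snps$id)
  c1 <- filter_call_rate(gm, 0.9)$gm
  expect_equal(unname(filter_call_rate(c1, 0.9)$gm$dosage), unname(c1$dosage))
  h1 <- filter_hwe(gm, 1e-3)$gm
  expect_equal(filter_hwe(h1, 1e-3)$gm$snps$id, h1$snps$id)
})
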