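test_that("Reynolds distance: identical, fixed-difference and monotone cases", {
  p <- runif(50, 0.1, 0.9)
  expect_equal(reynolds_distance(p, p), 0)
  expect_equal(reynolds_distance(rep(1, 30), rep(0, 30)), 1)
  # direct evaluation of the formula on a small fixture
  pA <- c(0.2, 0.5); pB <- c(0.4, 0.9)
  num <- sum((pA - pB)^2)
  den <- sum(1 - pA * pB - (1 - pA) * (1 - pB))
  expect_equal(reynolds_distance(pA, pB), num / den)
})

test_that("Reynolds distance grows with split time in neutral simulations", {
  d_short <- mean(sapply(1:3, function(s) {
    sim <- quick_sim(seed = 100 + s, m = 200, split_g = 5)
    reynolds_distance(allele_freq(sim$gm, "A"), allele_freq(sim$gm, "B"))
  }))
  d_long <- mean(sapply(1:3, function(s) {
    sim <- quick_sim(seed = 100 + s, m = 200, split_g = 60)
    reynolds_distance(allele_freq(sim$gm, "A"), allele_freq(sim$gm, "B"))
  }))
  expect_gt(d_long, d_short)
})

test_that("two-population kinship is diagonal and degenerate at D = 0", {
  k <- build_kinship(0.1, c("A", "B"))
  expect_equal(unname(diag(k$F)), c(0.1, 0.1))
  expect_equal(k$F[1, 2], 0)
  expect_false(k$degenerate)
  expect_true(build_kinship(0)$degenerate)
  expect_true(all(eigen(k$F)$values >= 0))
})

test_that("FLK matches the hand-derived two-population closed form", {
  D <- 0.08
  kin <- build_kinship(D)
  # explicit 2x2 algebra: p0 = (pA+pB)/2, FLK = (pA-pB)^2 / (2 p0 q0 D)
  set.seed(6)
  pA <- runif(40, 0.05, 0.95); pB <- runif(40, 0.05, 0.95)
  want <- (pA - pB)^2 / (2 * ((pA + pB) / 2) * (1 - (pA + pB) / 2) * D)
  expect_equal(flk(rbind(pA, pB), kin), want, tolerance = 1e-12)
  # no differentiation -> 0
  expect_equal(flk(c(0.3, 0.3), kin), 0)
  # monomorphic overall -> flagged
  expect_true(is.na(flk(c(0, 0), kin)))
  # allele relabelling invariance
  expect_equal(flk(rbind(pA, pB), kin), flk(rbind(1 - pA, 1 - pB), kin),
               tolerance = 1e-12)
})

test_that("cluster EM separates a two-haplotype mixture and is reproducible", {
  set.seed(9)
  h1 <- rbinom(40, 1, 0.5)
  h2 <- 1L - h1
  hap <- rbind(matrix(h1, 12, 40, byrow = TRUE),
               matrix(h2, 8, 40, byrow = TRUE))
  fit <- fit_hap_clusters(hap, K = 2, seed = 4)
  # posterior memberships recover the two haplotypes
  own <- apply(fit$gamma[, 20, ], 1, max)
  expect_true(all(own >= 0.95))
  lab <- apply(fit$gamma[, 20, ], 1, which.max)
  expect_equal(length(unique(lab[1:12])), 1L)
  expect_true(lab[1] != lab[13])
  # log-likelihood non-decreasing across EM iterations
  expect_true(all(diff(fit$loglik_trace) >= -1e-6 * abs(fit$loglik)))
  # seeded reproducibility
  fit2 <- fit_hap_clusters(hap, K = 2, seed = 4)
  expect_identical(fit$loglik, fit2$loglik)
  expect_identical(fit$theta, fit2$theta)
  expect_error(fit_hap_clusters(hap[1:3, ], K = 5), "exceeds")
})

test_that("EM log-likelihood is monotone on generic panels", {
  rp <- random_panel(n_ind = 10, m = 50, seed = 13)
  for (s in 1:3) {
    fit <- fit_hap_clusters(rp$panel, K = 2, seed = s)
    expect_true(all(diff(fit$loglik_trace) >= -1e-6 * abs(fit$loglik)))
  }
})

test_that("hapFLK: zero under identical frequencies, nfit averaging, sensitivity", {
  kin <- build_kinship(0.05)
  # symmetric panel: both populations carry the same haplotype multiset
  set.seed(15)
  base <- matrix(rbinom(10 * 30, 1, 0.5), 10, 30)
  hap <- rbind(base, base)
  pop <- rep(c("A", "B"), each = 10)
  fit <- fit_hap_clusters(hap, K = 2, seed = 2)
  v <- hapflk_statistic(list(fit), pop, kin)
  expect_true(all(v < 1e-10))
  # a duplicated fit averages to the single-fit value
  rp <- random_panel(n_ind = 12, m = 40, seed = 19,
                     pop = rep(c("A", "B"), each = 6))
  f1 <- fit_hap_clusters(rp$panel, K = 2, seed = 7)
  pop2 <- rep(rp$panel$samples$pop, each = 2)
  expect_equal(hapflk_statistic(list(f1, f1), pop2, kin),
               hapflk_statistic(list(f1), pop2, kin))
  # haplotype structure invisible to single-SNP frequencies: population A is
  # two complementary haplotypes at 50/50; population B holds four random
  # mosaics with exactly two carriers of allele 1 per SNP, so every per-SNP
  # allele frequency is exactly 0.5 in both populations and FLK is 0, while
  # the cluster frequencies still separate the populations locally
  set.seed(31)
  m3 <- 24
  h1 <- rbinom(m3, 1, 0.5)
  hA <- rbind(matrix(h1, 10, m3, byrow = TRUE),
              matrix(1L - h1, 10, m3, byrow = TRUE))
  bset <- sapply(seq_len(m3), function(j) {
    v <- integer(4); v[sample.int(4, 2)] <- 1L; v
  })
  hB <- bset[rep(1:4, each = 5), ]
  hap3 <- rbind(hA, hB)
  pop3 <- rep(c("A", "B"), each = 20)
  pa <- colMeans(hap3[pop3 == "A", ]); pb <- colMeans(hap3[pop3 == "B", ])
  expect_equal(pa, pb)   # both exactly 0.5 everywhere
  flk_vals <- flk(rbind(pa, pb), kin)
  expect_true(all(abs(flk_vals) < 1e-10))
  v3 <- rowMeans(sapply(1:3, function(s)
    hapflk_statistic(list(fit_hap_clusters(hap3, K = 2, seed = s)), pop3, kin)))
  expect_gt(mean(v3), 0.5)
})

test_that("q-value calling: BH oracle agreement and degenerate input", {
  set.seed(23)
  vals <- rchisq(2000, df = 1) * 0.8
  calls <- call_hapflk(vals, q_threshold = 0.01)
  expect_equal(calls$q, bh_oracle(calls$p), tolerance = 1e-12)
  # q monotone in p
  o <- order(calls$p)
  expect_true(all(diff(calls$q[o]) >= -1e-12))
  # near-null input: approximately no flags
  expect_lte(sum(calls$flag), 2)
  # all-equal statistics: no flags
  same <- suppressWarnings(call_hapflk(rep(1.3, 1500)))
  expect_equal(sum(same$flag), 0L)
})

test_that("full scan wires kinship, FLK, EM fits and calls together", {
  sim <- quick_sim(seed = 44, m = 150)
  sc <- suppressWarnings(hapflk_scan(sim$gm, sim$panel, nfit = 2,
                                     max_iter = 15, seed = 5))
  expect_equal(nrow(sc$track), 150L)
  expect_true(all(is.finite(sc$track$hapflk)))
  expect_gt(sc$kinship$D, 0)
  # rerun with the same seed is identical
  sc2 <- suppressWarnings(hapflk_scan(sim$gm, sim$panel, nfit = 2,
                                      max_iter = 15, seed = 5))
  expect_identical(sc$track$hapflk, sc2$track$hapflk)
})
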