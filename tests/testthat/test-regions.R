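test_that("flagged SNPs merge by gap distance", {
  map <- data.frame(chrom = c(1L, 1L, 1L, 2L), bp = c(1e6, 1.4e6, 2.0e6, 1e6),
                    stat = c(3, 5, 4, 9))
  r <- merge_flagged_snps(c(TRUE, TRUE, TRUE, TRUE), map, merge_gap = 5e5,
                          method = "X", stat = "stat")
  expect_equal(nrow(r), 3L)   # 400 kb joins, 600 kb splits, chrom 2 separate
  expect_equal(r$start_bp[1], 1e6)
  expect_equal(r$end_bp[1], 1.4e6)
  expect_equal(r$peak_stat[1], 5)
  expect_equal(r$n_snps, c(2L, 1L, 1L))
  expect_equal(nrow(merge_flagged_snps(c(FALSE, FALSE, FALSE, FALSE), map)), 0L)
})

test_that("merging matches an interval-union oracle and is idempotent", {
  skip_if_not_installed("IRanges")
  for (seed in 1:10) {
    set.seed(seed)
    m <- 60
    map <- data.frame(chrom = sort(sample(1:3, m, TRUE)),
                      bp = NA_real_)
    map$bp <- unlist(lapply(split(seq_len(m), map$chrom), function(i)
      sort(sample.int(2e7, length(i)))))
    flags <- runif(m) < 0.3
    got <- merge_flagged_snps(flags, map, merge_gap = 5e5)
    # oracle: expand each flagged point by half the gap and reduce
    want_n <- 0L
    for (ch in unique(map$chrom[flags])) {
      bp <- map$bp[flags & map$chrom == ch]
      ir <- IRanges::reduce(IRanges::IRanges(start = bp, end = bp + 5e5))
      want_n <- want_n + length(ir)
    }
    expect_equal(nrow(got), want_n, info = paste("seed", seed))
    # idempotence: merging the merged starts changes nothing
    if (nrow(got)) {
      again <- merge_flagged_snps(rep(TRUE, nrow(got)),
                                  data.frame(chrom = got$chrom,
                                             bp = got$start_bp),
                                  merge_gap = 5e5)
      expect_lte(nrow(again), nrow(got))
    }
  }
})

test_that("consensus requires two methods and groups transitively", {
  r <- data.frame(chrom = 26L, start_bp = c(4.76e6, 4.8e6),
                  end_bp = c(5.89e6, 5.5e6), method = c("FST", "HAPFLK"),
                  n_snps = 1L, peak_stat = 1)
  cons <- consensus_regions(r, flank = 5e5)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$methods, "FST,HAPFLK")
  expect_equal(cons$support, 2L)
  # single-method region never emitted
  expect_equal(nrow(consensus_regions(r[1, ], flank = 5e5)), 0L)
  # same method twice is support 1
  r2 <- r; r2$method <- "FST"
  expect_equal(nrow(consensus_regions(r2, flank = 5e5)), 0L)
  # three-way chain: A-B overlap, B-C overlap, A-C do not; all one group
  chain <- data.frame(chrom = 1L,
                      start_bp = c(1e6, 1.8e6, 2.6e6),
                      end_bp = c(1.1e6, 1.9e6, 2.7e6),
                      method = c("FST", "XPEHH", "HAPFLK"),
                      n_snps = 1L, peak_stat = 1)
  cc <- consensus_regions(chain, flank = 5e5)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$support, 3L)
  expect_equal(cc$start_bp, 1e6)
  expect_equal(cc$end_bp, 2.7e6)
  # symmetric in method order
  cc2 <- consensus_regions(chain[3:1, ], flank = 5e5)
  expect_equal(cc, cc2)
})

test_that("consensus grouping matches a graph-components oracle", {
  skip_if_not_installed("IRanges")
  for (seed in 1:8) {
    set.seed(seed)
    n <- 12
    st <- sort(sample.int(3e7, n))
    r <- data.frame(chrom = 1L, start_bp = st,
                    end_bp = st + sample.int(8e5, n),
                    method = sample(c("FST", "XPEHH", "HAPFLK"), n, TRUE),
                    n_snps = 1L, peak_stat = 1)
    got <- consensus_regions(r, flank = 5e5)
    # oracle: overlap graph components via IRanges
    ir <- IRanges::IRanges(start = pmax(r$start_bp - 5e5, 0),
                           end = r$end_bp + 5e5)
    comp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, IRanges::reduce(ir)))
    want <- 0L
    for (g in unique(comp)) {
      if (length(unique(r$method[comp == g])) >= 2) want <- want + 1L
    }
    expect_equal(nrow(got), want, info = paste("seed", seed))
  }
})

test_that("gene annotation respects the 500 kb flank", {
  regions <- data.frame(chrom = 1L, start_bp = 2e6, end_bp = 3e6)
  genes <- data.frame(chrom = c(1L, 1L, 2L),
                      start_bp = c(3.3e6, 3.7e6, 2.5e6),
                      end_bp = c(3.4e6, 3.8e6, 2.6e6),
                      gene = c("NEAR", "FAR", "OTHERCHR"))
  ann <- annotate_regions(regions, genes, flank = 5e5)
  expect_equal(ann$gene, "NEAR")   # 300 kb away in; 600 kb away out
  # brute-force all-pairs oracle on a random fixture
  set.seed(7)
  rr <- data.frame(chrom = sample(1:2, 6, TRUE),
                   start_bp = sample.int(1e7, 6), end_bp = NA_real_)
  rr$end_bp <- rr$start_bp + sample.int(5e5, 6)
  gg <- data.frame(chrom = sample(1:2, 15, TRUE),
                   start_bp = sample.int(1.2e7, 15), end_bp = NA_real_,
                   gene = paste0("g", 1:15))
  gg$end_bp <- gg$start_bp + sample.int(2e5, 15)
  ann2 <- annotate_regions(rr, gg, flank = 5e5)
  want <- 0L
  for (i in seq_len(nrow(rr))) for (j in seq_len(nrow(gg))) {
    if (rr$chrom[i] == gg$chrom[j] &&
        gg$start_bp[j] <= rr$end_bp[i] + 5e5 &&
        gg$end_bp[j] >= rr$start_bp[i] - 5e5) want <- want + 1L
  }
  expect_equal(nrow(ann2), want)
})

test_that("gene tables load from GFF3 via rtracklayer", {
  skip_if_not_installed("rtracklayer")
  td <- withr::local_tempdir()
  gff <- file.path(td, "genes.gff3")
  writeLines(c("##gff-version 3",
               "1\ttest\tgene\t3300000\t3400000\t.\t+\t.\tID=gene1;Name=NEAR",
               "1\ttest\tgene\t9000000\t9100000\t.\t-\t.\tID=gene2;Name=FAR"),
             gff)
  ann <- annotate_regions(data.frame(chrom = 1L, start_bp = 2e6, end_bp = 3e6),
                          gff, flank = 5e5)
  expect_equal(ann$gene, "NEAR")
  expect_equal(ann$gene_start_bp, 3300000)
})
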