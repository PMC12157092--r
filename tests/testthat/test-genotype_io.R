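test_that("PED/MAP reading applies the minor-allele polarity rule", {
  td <- withr::local_tempdir()
  writeLines(c("1\ts1\t0\t100", "1\ts2\t0\t200"), file.path(td, "f.map"))
  writeLines(c("P1 ind1 0 0 0 -9 A A A G",
               "P1 ind2 0 0 0 -9 A A G G",
               "P2 ind3 0 0 0 -9 A A 0 0"),
             file.path(td, "f.ped"))
  gm <- read_plink(file.path(td, "f.map"), file.path(td, "f.ped"))
  expect_equal(n_ind(gm), 3L)
  expect_equal(gm$snps$id, c("s1", "s2"))
  # s1 monomorphic A: dosage 0 everywhere
  expect_equal(gm$dosage[, 1], c(0L, 0L, 0L))
  # s2: alleles A (1 copy), G (3 copies) -> allele_b = A (minor)
  expect_equal(gm$snps$allele_b[2], "A")
  expect_equal(gm$dosage[, 2], c(1L, 0L, NA_integer_))
  expect_equal(gm$samples$pop, c("P1", "P1", "P2"))
})

test_that("PED/MAP structural errors are reported", {
  td <- withr::local_tempdir()
  writeLines(c("1\ts1\t0\t100", "1\ts2\t0\t200"), file.path(td, "f.map"))
  writeLines("P1 ind1 0 0 0 -9 A A", file.path(td, "f.ped"))
  expect_error(read_plink(file.path(td, "f.map"), file.path(td, "f.ped")),
               "mismatch")
  writeLines(c("P1 ind1 0 0 0 -9 A A A G",
               "P1 ind1 0 0 0 -9 A A A G"), file.path(td, "f.ped"))
  expect_error(read_plink(file.path(td, "f.map"), file.path(td, "f.ped")),
               "duplicate")
})

test_that("PLINK round-trip preserves dosage, map and labels", {
  td <- withr::local_tempdir()
  for (seed in 1:5) {
    gm0 <- random_gm(n = 8, m = 15, miss = 0.1, n_chrom = 2, seed = seed)
    # first cycle re-polarises dosages to the loader's minor-allele rule;
    # genotypes must survive up to that per-SNP polarity flip
    write_plink(gm0, file.path(td, "rt"))
    gm <- read_plink(file.path(td, "rt.map"), file.path(td, "rt.ped"))
    flip_ok <- sapply(seq_len(n_snp(gm0)), function(j) {
      a <- gm0$dosage[, j]; b <- gm$dosage[, j]
      identical(is.na(a), is.na(b)) &&
        (all(a == b, na.rm = TRUE) || all(a == 2L - b, na.rm = TRUE))
    })
    expect_true(all(flip_ok))
    # from the loaded representation the round trip is exact
    write_plink(gm, file.path(td, "rt2"))
    gm2 <- read_plink(file.path(td, "rt2.map"), file.path(td, "rt2.ped"))
    expect_equal(unname(gm2$dosage), unname(gm$dosage))
    expect_equal(gm2$snps$id, gm$snps$id)
    expect_equal(gm2$snps$bp, gm$snps$bp)
    expect_equal(gm2$snps$chrom, gm$snps$chrom)
    expect_equal(gm2$samples$iid, gm$samples$iid)
    expect_equal(gm2$samples$pop, gm$samples$pop)
  }
})

test_that("loading keeps individual order and sorts SNPs uniquely", {
  d <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
  gm <- genotype_matrix(d,
    snps = data.frame(id = c("b", "a"), chrom = c(1L, 1L), bp = c(500L, 100L),
                      allele_a = "A", allele_b = "B"),
    samples = data.frame(iid = c("z", "y"), pop = "P"))
  expect_equal(gm$snps$id, c("a", "b"))
  expect_equal(gm$samples$iid, c("z", "y"))
  expect_equal(gm$dosage[, 1], c(2L, 0L))
})

test_that("empty-SNP matrix writes a valid 0-row MAP and PED metadata", {
  td <- withr::local_tempdir()
  gm <- make_gm(matrix(integer(), 2, 0), chrom = integer(), bp = numeric())
  write_plink(gm, file.path(td, "empty"))
  expect_equal(length(readLines(file.path(td, "empty.map"))), 0L)
  ped <- readLines(file.path(td, "empty.ped"))
  expect_equal(length(ped), 2L)
  expect_equal(length(strsplit(ped[1], " ")[[1]]), 6L)
})

test_that("haplotype tables round-trip and are validated against dosage", {
  td <- withr::local_tempdir()
  rp <- random_panel(n_ind = 6, m = 12, seed = 2)
  path <- file.path(td, "hap.tsv")
  write_haplotypes(rp$panel, path)
  p2 <- read_haplotypes(path, rp$gm)
  expect_equal(unname(p2$hap), unname(rp$panel$hap))
  # wrong row count
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  write.table(tab[-1, ], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_haplotypes(path, rp$gm), "rows")
  # dosage inconsistency
  hap <- rp$panel$hap
  hap[1, 1] <- 1L - hap[1, 1]
  expect_error(haplotype_panel(hap, rp$gm), "disagree")
})

test_that("BED output is 0-based half-open while internals stay 1-based", {
  td <- withr::local_tempdir()
  path <- file.path(td, "r.bed")
  write_bed_regions(data.frame(chrom = 26L, start_bp = 4760000,
                               end_bp = 5890000), path)
  expect_equal(readLines(path), "26\t4759999\t5890000")
  write_bed_regions(data.frame(chrom = integer(), start_bp = numeric(),
                               end_bp = numeric()), path)
  expect_equal(length(readLines(path)), 0L)
  # overlapping regions preserved as given
  r <- data.frame(chrom = c(1L, 1L), start_bp = c(100, 150), end_bp = c(200, 250))
  write_bed_regions(r, path)
  expect_equal(length(readLines(path)), 2L)
  expect_error(write_bed_regions(data.frame(chrom = 1L, start_bp = 10,
                                            end_bp = 5), path), "start_bp")
})
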