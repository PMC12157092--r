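#' Read PLINK text PED/MAP files
#'
#' Loads a diploid genotype matrix from the classic PLINK text pair. The MAP
#' file has four whitespace-separated columns (chromosome, SNP id, genetic
#' position, bp); the PED file has six metadata columns (FID IID PAT MAT SEX
#' PHENO) followed by two allele columns per SNP, with "0" marking a missing
#' allele. The PED family id is taken as the population label.
#'
#' `allele_b` (the dosage-counted allele) is defined as the minor allele
#' across all individuals at load time; ties are broken by taking the
#' lexicographically greater allele. Heterozygotes are coded 1 regardless of
#' allele order in the PED.
#'
#' @param map_path path to the .map file.
#' @param ped_path path to the .ped file.
#' @return A [genotype_matrix()] with SNPs sorted by (chrom, bp).
#' @export
read_plink <- function(map_path, ped_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "bp"),
                           colClasses = c("integer", "character", "numeric", "integer"))
  m <- nrow(map)
  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  n <- length(fields)
  if (n == 0L) stop("PED file has no individuals")
  len <- lengths(fields)
  if (any(len != 6L + 2L * m))
    stop("PED/MAP mismatch: expected ", 6L + 2L * m,
         " fields per PED line, found ", paste(unique(len[len != 6L + 2L * m]), collapse = ","))
  meta <- t(vapply(fields, function(f) f[1:6], character(6)))
  iid <- meta[, 2]
  if (anyDuplicated(iid)) stop("duplicate individual ids in PED")
  pop <- meta[, 1]

  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  i1 <- 6L + seq(1L, 2L * m, by = 2L)
  for (k in seq_len(n)) {
    a1[k, ] <- fields[[k]][i1]
    a2[k, ] <- fields[[k]][i1 + 1L]
  }

  dosage <- matrix(NA_integer_, n, m)
  allele_a <- character(m)
  allele_b <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- c(x1[!miss], x2[!miss])
    al <- sort(unique(obs))
    if (length(al) > 2L)
      stop("SNP ", map$id[j], " has more than two alleles")
    if (length(al) == 0L) {
      allele_a[j] <- "0"; allele_b[j] <- "0"
      next
    }
    if (length(al) == 1L) {
      allele_a[j] <- al; allele_b[j] <- "0"
      dosage[!miss, j] <- 0L
      next
    }
    cnt <- c(sum(obs == al[1]), sum(obs == al[2]))
    # minor allele = allele_b; tie -> lexicographically greater
    bi <- if (cnt[1] < cnt[2]) 1L else if (cnt[2] < cnt[1]) 2L else 2L
    allele_b[j] <- al[bi]; allele_a[j] <- al[3L - bi]
    dosage[!miss, j] <- (x1[!miss] == allele_b[j]) + (x2[!miss] == allele_b[j])
  }

  genotype_matrix(dosage,
                  snps = data.frame(id = map$id, chrom = map$chrom, bp = map$bp,
                                    allele_a = allele_a, allele_b = allele_b,
                                    stringsAsFactors = FALSE),
                  samples = data.frame(iid = iid, pop = pop, stringsAsFactors = FALSE))
}

#' Write PLINK text PED/MAP files
#'
#' Inverse of [read_plink()]: `read_plink(write_plink(gm))` reproduces the
#' dosage table, map and labels exactly (up to the allele-polarity rule,
#' which is stable because dosages encode the minor allele).
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_plink <- function(gm, prefix) {
  map <- data.frame(chrom = gm$snps$chrom, id = gm$snps$id,
                    cm = rep(0, n_snp(gm)), bp = gm$snps$bp)
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  m <- n_snp(gm)
  aa <- gm$snps$allele_a; ab <- gm$snps$allele_b
  # monomorphic SNPs carry "0" as allele_b; dosage there is 0 => allele_a pairs
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (k in seq_len(n_ind(gm))) {
    d <- gm$dosage[k, ]
    x1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, ab, aa))
    x2 <- ifelse(is.na(d), "0", ifelse(d == 2L, ab, aa))
    line <- c(gm$samples$pop[k], gm$samples$iid[k], "0", "0", "0", "-9",
              as.vector(rbind(x1, x2)))
    writeLines(paste(line, collapse = " "), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Read / write a plain-text haplotype table
#'
#' The haplotype table is tab-separated with a header row
#' `iid<TAB>hap<TAB><snp ids...>`; each body row is one haplotype (`hap` is 1
#' or 2 within individual), entries 0/1 coding allele_a/allele_b. Rows appear
#' in the individual order of the companion genotype matrix.
#'
#' @param path file path.
#' @param gm companion [genotype_matrix()] used to check consistency.
#' @return [read_haplotypes()] returns a [haplotype_panel()];
#'   `write_haplotypes` invisibly returns `path`.
#' @export
read_haplotypes <- function(path, gm) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 2L + n_snp(gm))
    stop("haplotype table has ", ncol(tab) - 2L, " SNP columns, expected ", n_snp(gm))
  if (nrow(tab) != 2L * n_ind(gm))
    stop("haplotype table has ", nrow(tab), " rows, expected ", 2L * n_ind(gm))
  hap <- as.matrix(tab[, -(1:2), drop = FALSE])
  haplotype_panel(hap, gm)
}

#' @rdname read_haplotypes
#' @param panel a [haplotype_panel()].
#' @export
write_haplotypes <- function(panel, path) {
  out <- data.frame(iid = rep(panel$samples$iid, each = 2L),
                    hap = rep(1:2, nrow(panel$samples)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(panel$hap))
  names(out) <- c("iid", "hap", panel$snps$id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write regions as BED3+
#'
#' Internal coordinates are 1-based inclusive bp (PLINK/MAP convention);
#' conversion to BED's 0-based half-open intervals happens here and only
#' here: `start0 = start_bp - 1`, `end0 = end_bp`.
#'
#' @param regions data.frame with columns `chrom`, `start_bp`, `end_bp` and
#'   optionally further columns (kept as BED extra fields, in order).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_bed_regions <- function(regions, path) {
  if (nrow(regions) > 0 && any(regions$start_bp > regions$end_bp))
    stop("region with start_bp > end_bp")
  extra <- setdiff(names(regions), c("chrom", "start_bp", "end_bp"))
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start_bp - 1L,
                    end = regions$end_bp)
  for (e in extra) bed[[e]] <- regions[[e]]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
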