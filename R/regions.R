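#' Merge flagged SNPs into candidate regions
#'
#' Flagged SNPs on the same chromosome are merged into one region whenever
#' consecutive flagged SNPs are at most `merge_gap` bp apart; region bounds
#' are the min/max member positions (1-based inclusive).
#'
#' @param flags logical vector, one per SNP.
#' @param map data.frame with `chrom`, `bp` (and optionally a statistic
#'   column named by `stat`).
#' @param merge_gap maximum gap between members (default 500 kb).
#' @param method label recorded on each region.
#' @param stat optional name of a statistic column in `map`; the region
#'   records its peak member value.
#' @return data.frame with `chrom`, `start_bp`, `end_bp`, `method`,
#'   `n_snps`, `peak_stat`.
#' @export
merge_flagged_snps <- function(flags, map, merge_gap = 5e5, method = "stat",
                               stat = NULL) {
  stopifnot(length(flags) == nrow(map))
  idx <- which(flags & !is.na(flags))
  empty <- data.frame(chrom = integer(), start_bp = numeric(),
                      end_bp = numeric(), method = character(),
                      n_snps = integer(), peak_stat = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(idx)) return(empty)
  rows <- list()
  for (ch in unique(map$chrom[idx])) {
    ii <- idx[map$chrom[idx] == ch]
    ii <- ii[order(map$bp[ii])]
    bp <- map$bp[ii]
    newgrp <- c(TRUE, diff(bp) > merge_gap)
    grp <- cumsum(newgrp)
    for (g in unique(grp)) {
      mem <- ii[grp == g]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start_bp = min(map$bp[mem]), end_bp = max(map$bp[mem]),
        method = method, n_snps = length(mem),
        peak_stat = if (!is.null(stat)) max(map[[stat]][mem], na.rm = TRUE)
                    else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start_bp), , drop = FALSE]
}

#' Cross-method consensus regions
#'
#' Regions from different methods whose `flank`-expanded intervals
#' intersect are grouped transitively (chain overlaps join); groups
#' supported by at least two distinct methods are emitted as consensus
#' regions with the merged (unexpanded) bounds.
#'
#' @param regions data.frame as from [merge_flagged_snps()], possibly the
#'   row-bind of several methods' regions.
#' @param flank expansion applied to each side before testing overlap
#'   (default 500 kb).
#' @param min_support minimum number of distinct supporting methods
#'   (default 2).
#' @return data.frame with `chrom`, `start_bp`, `end_bp`, `methods`
#'   (comma-joined, sorted), `support`.
#' @export
consensus_regions <- function(regions, flank = 5e5, min_support = 2L) {
  empty <- data.frame(chrom = integer(), start_bp = numeric(),
                      end_bp = numeric(), methods = character(),
                      support = integer(), stringsAsFactors = FALSE)
  if (!nrow(regions)) return(empty)
  rows <- list()
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    r <- r[order(r$start_bp, r$end_bp), , drop = FALSE]
    lo <- pmax(r$start_bp - flank, 0)
    hi <- r$end_bp + flank
    # transitive grouping along the sorted axis
    grp <- integer(nrow(r))
    grp[1] <- 1L
    reach <- hi[1]
    for (k in seq_len(nrow(r))[-1]) {
      if (lo[k] <= reach) grp[k] <- grp[k - 1L]
      else grp[k] <- grp[k - 1L] + 1L
      reach <- max(reach, hi[k])
    }
    for (g in unique(grp)) {
      mem <- which(grp == g)
      meths <- sort(unique(r$method[mem]))
      if (length(meths) < min_support) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start_bp = min(r$start_bp[mem]),
        end_bp = max(r$end_bp[mem]),
        methods = paste(meths, collapse = ","),
        support = length(meths), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start_bp), , drop = FALSE]
}

#' Annotate regions with overlapping gene intervals
#'
#' Interval intersection of `flank`-expanded regions against a user-supplied
#' gene table; no database access. The gene table can be a data.frame
#' (`chrom`, `start_bp`, `end_bp`, `gene`) or a path to a BED or GFF3 file
#' (read via rtracklayer; BED input is converted from 0-based half-open to
#' the package's 1-based inclusive convention).
#'
#' @param regions data.frame with `chrom`, `start_bp`, `end_bp`.
#' @param gene_table data.frame or file path.
#' @param flank expansion per side (default 500 kb).
#' @return data.frame of region-gene pairs: region columns plus `gene`,
#'   `gene_start_bp`, `gene_end_bp`.
#' @export
annotate_regions <- function(regions, gene_table, flank = 5e5) {
  genes <- read_gene_table(gene_table)
  rows <- list()
  for (k in seq_len(nrow(regions))) {
    lo <- regions$start_bp[k] - flank
    hi <- regions$end_bp[k] + flank
    hit <- genes$chrom == regions$chrom[k] &
      genes$start_bp <= hi & genes$end_bp >= lo
    for (gi in which(hit)) {
      rows[[length(rows) + 1L]] <- cbind(
        regions[k, c("chrom", "start_bp", "end_bp"), drop = FALSE],
        data.frame(gene = genes$gene[gi],
                   gene_start_bp = genes$start_bp[gi],
                   gene_end_bp = genes$end_bp[gi],
                   stringsAsFactors = FALSE))
    }
  }
  if (!length(rows))
    return(data.frame(chrom = integer(), start_bp = numeric(),
                      end_bp = numeric(), gene = character(),
                      gene_start_bp = numeric(), gene_end_bp = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

read_gene_table <- function(gene_table) {
  if (is.data.frame(gene_table)) {
    stopifnot(all(c("chrom", "start_bp", "end_bp", "gene") %in% names(gene_table)))
    return(gene_table)
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading gene files requires the rtracklayer package; ",
         "pass a data.frame instead")
  df <- as.data.frame(rtracklayer::import(gene_table))
  nm <- if (!is.null(df$Name)) df$Name
        else if (!is.null(df$name)) df$name
        else if (!is.null(df$ID)) df$ID
        else paste0("feature", seq_len(nrow(df)))
  data.frame(chrom = as.integer(as.character(df$seqnames)),
             start_bp = df$start,   # rtracklayer yields 1-based inclusive
             end_bp = df$end,
             gene = as.character(nm), stringsAsFactors = FALSE)
}
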