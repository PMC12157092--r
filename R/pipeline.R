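#' Pipeline configuration
#'
#' Assembles (and validates) the declarative configuration for
#' [run_pipeline()]. Input is either a simulation (`sim` = a [sim_config()])
#' or files (`ped`/`map`, optionally `haplotypes`). Every stage draws its
#' randomness from `seed` via fixed stage offsets, so a rerun with the same
#' config is byte-identical on all tables.
#'
#' @param input list: either `list(sim = sim_config(...))` or
#'   `list(ped = path, map = path, haplotypes = path_or_NULL)`.
#' @param seed root seed for all stages.
#' @param qc list of [run_qc()] arguments (or `NULL` to skip).
#' @param roh [roh_params()] (or `NULL` to skip the ROH stage).
#' @param ne [ne_config()] (or `NULL` to skip).
#' @param pca `list(n_components = )` or `NULL`.
#' @param fst list of [fst_scan()] arguments or `NULL`.
#' @param xpehh list of [xpehh_scan()] arguments or `NULL` (needs phased
#'   haplotypes).
#' @param hapflk list of [hapflk_scan()] arguments or `NULL` (needs phased
#'   haplotypes).
#' @param regions `list(merge_gap = , flank = )` consensus settings.
#' @param gene_table optional gene table (data.frame or BED/GFF3 path) for
#'   region annotation.
#' @param plots write PDF figures (default FALSE).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, seed = 1L,
                            qc = list(), roh = roh_params(), ne = ne_config(),
                            pca = list(n_components = 2L),
                            fst = list(), xpehh = list(), hapflk = list(),
                            regions = list(merge_gap = 5e5, flank = 5e5),
                            gene_table = NULL, plots = FALSE) {
  if (is.null(input$sim) && (is.null(input$ped) || is.null(input$map)))
    stop("config validation: input needs either 'sim' or 'ped'+'map'")
  structure(list(input = input, seed = as.integer(seed), qc = qc, roh = roh,
                 ne = ne, pca = pca, fst = fst, xpehh = xpehh,
                 hapflk = hapflk, regions = regions, gene_table = gene_table,
                 plots = isTRUE(plots)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the [pipeline_config()] arguments; `input.sim` holds
#' [sim_config()] arguments, `roh` holds [roh_params()] arguments, `ne`
#' holds [ne_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the yaml package")
  y <- yaml::read_yaml(path)
  if (!is.null(y$input$sim)) y$input$sim <- do.call(sim_config, y$input$sim)
  if (!is.null(y$roh)) y$roh <- do.call(roh_params, y$roh)
  if (!is.null(y$ne)) y$ne <- do.call(ne_config, y$ne)
  do.call(pipeline_config, y)
}

.stage_seed <- function(root, k) (root * 131L + k) %% 2147483629L

.tsv <- function(x, dir, name) {
  utils::write.table(as.data.frame(x), file.path(dir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates: input (simulation or PLINK files) -> QC -> ROH/F_ROH ->
#' per-population Ne trajectories -> PCA -> the three selection scans ->
#' per-method candidate regions -> cross-method consensus -> optional gene
#' annotation. All tables are written as TSV under `out_dir`; a `log.txt`
#' records stage progression. Any stage failure aborts with a stage-tagged
#' message.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  cat("", file = logf)
  note <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                            append = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    note("stage %-10s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    r
  }
  res <- list()

  res$input <- stage("input", {
    if (!is.null(config$input$sim)) {
      sim <- config$input$sim
      sim$seed <- .stage_seed(config$seed, 1L)
      out <- sim_population(sim)
      .tsv(out$truth$ne, out_dir, "truth_ne.tsv")
      if (!is.null(out$truth$autozygosity))
        .tsv(out$truth$autozygosity, out_dir, "truth_autozygosity.tsv")
      out
    } else {
      gm <- read_plink(config$input$map, config$input$ped)
      panel <- if (!is.null(config$input$haplotypes))
        read_haplotypes(config$input$haplotypes, gm) else NULL
      list(gm = gm, panel = panel, truth = NULL)
    }
  })
  gm <- res$input$gm
  panel <- res$input$panel

  if (!is.null(config$qc)) {
    res$qc <- stage("qc", do.call(run_qc, c(list(gm = gm,
                                                 seed = .stage_seed(config$seed, 2L)),
                                            config$qc)))
    write_qc_report(res$qc$report, file.path(out_dir, "qc_report.tsv"))
    gm <- res$qc$gm
    if (!is.null(panel)) {
      keep <- match(gm$snps$id, panel$snps$id)
      hap <- panel$hap[, keep, drop = FALSE]
      panel <- if (anyNA(gm$dosage)) NULL else
        tryCatch(haplotype_panel(hap, gm), error = function(e) NULL)
      if (is.null(panel)) note("haplotype panel dropped after QC (dosage changes)")
    }
  }

  pops <- unique(gm$samples$pop)

  if (!is.null(config$roh)) {
    res$roh <- stage("roh", {
      seg <- detect_roh(gm, config$roh)
      list(segments = seg, froh = froh(seg, gm),
           summary = summarize_roh(seg, gm))
    })
    write_roh_segments(res$roh$segments, file.path(out_dir, "roh_segments.tsv"))
    .tsv(res$roh$froh, out_dir, "froh.tsv")
    .tsv(res$roh$summary$class_mean_sum, out_dir, "roh_class_mean_sum.tsv")
    .tsv(res$roh$summary$per_chromosome, out_dir, "roh_per_chromosome.tsv")
  }

  if (!is.null(config$ne)) {
    res$ne <- stage("ne", {
      lapply(stats::setNames(pops, pops), function(pp) {
        rec <- do.call(rbind, lapply(unique(gm$snps$chrom), function(ch)
          pairwise_r2(gm, ch, max_dist_bp = max(config$ne$bins), pop = pp,
                      min_maf = config$ne$min_maf)))
        estimate_ne(rec, config$ne)
      })
    })
    for (pp in pops)
      write_ne_trajectory(res$ne[[pp]], file.path(out_dir,
                                                  paste0("ne_", pp, ".tsv")))
  }

  if (!is.null(config$pca)) {
    res$pca <- stage("pca", {
      g2 <- if (anyNA(gm$dosage))
        impute_naive(gm, .stage_seed(config$seed, 3L)) else gm
      do.call(snp_pca, c(list(gm = g2), config$pca))
    })
    .tsv(cbind(res$pca$samples, res$pca$scores), out_dir, "pca_scores.tsv")
    .tsv(data.frame(component = seq_along(res$pca$varprop),
                    varprop = res$pca$varprop), out_dir, "pca_varprop.tsv")
  }

  region_sets <- list()
  if (!is.null(config$fst)) {
    res$fst <- stage("fst", do.call(fst_scan, c(list(gm = gm), config$fst)))
    .tsv(res$fst$snp, out_dir, "fst_snp.tsv")
    .tsv(res$fst$window, out_dir, "fst_window.tsv")
    flag_snp <- res$fst$window$flag[match(res$fst$snp$window,
                                          res$fst$window$window)]
    region_sets$FST <- merge_flagged_snps(flag_snp, res$fst$snp,
                                          config$regions$merge_gap,
                                          method = "FST", stat = "smoothed")
  }
  if (!is.null(config$xpehh) && !is.null(panel)) {
    res$xpehh <- stage("xpehh",
                       do.call(xpehh_scan, c(list(panel = panel), config$xpehh)))
    .tsv(as.data.frame(res$xpehh), out_dir, "xpehh_track.tsv")
    region_sets$XPEHH <- merge_flagged_snps(
      res$xpehh$flag_a | res$xpehh$flag_b, res$xpehh,
      config$regions$merge_gap, method = "XPEHH", stat = "z")
  }
  if (!is.null(config$hapflk) && !is.null(panel)) {
    res$hapflk <- stage("hapflk",
                        do.call(hapflk_scan,
                                c(list(gm = gm, panel = panel,
                                       seed = .stage_seed(config$seed, 4L)),
                                  config$hapflk)))
    .tsv(res$hapflk$track, out_dir, "hapflk_track.tsv")
    region_sets$HAPFLK <- merge_flagged_snps(res$hapflk$track$flag,
                                             res$hapflk$track,
                                             config$regions$merge_gap,
                                             method = "HAPFLK", stat = "hapflk")
  }

  if (length(region_sets)) {
    res$regions <- stage("regions", {
      all_regions <- do.call(rbind, region_sets)
      cons <- consensus_regions(all_regions, config$regions$flank)
      ann <- if (!is.null(config$gene_table) && nrow(all_regions))
        annotate_regions(all_regions, config$gene_table,
                         config$regions$flank) else NULL
      list(by_method = all_regions, consensus = cons, genes = ann)
    })
    .tsv(res$regions$by_method, out_dir, "regions_by_method.tsv")
    .tsv(res$regions$consensus, out_dir, "regions_consensus.tsv")
    if (nrow(res$regions$by_method))
      write_bed_regions(res$regions$by_method,
                        file.path(out_dir, "regions_by_method.bed"))
    if (!is.null(res$regions$genes))
      .tsv(res$regions$genes, out_dir, "region_genes.tsv")
  }

  if (config$plots) stage("plots", .pipeline_plots(res, out_dir))
  note("pipeline complete")
  invisible(res)
}

.pipeline_plots <- function(res, out_dir) {
  pdf_of <- function(name, expr) {
    grDevices::pdf(file.path(out_dir, name), width = 8, height = 5)
    on.exit(grDevices::dev.off())
    expr
  }
  if (!is.null(res$pca)) pdf_of("pca.pdf", plot(res$pca))
  if (!is.null(res$ne))
    pdf_of("ne.pdf", {
      first <- TRUE
      for (pp in names(res$ne)) {
        tr <- res$ne[[pp]]
        if (first) { plot(tr, main = "Ne trajectories"); first <- FALSE }
        else graphics::lines(tr$gens_ago[tr$valid], tr$ne[tr$valid],
                             type = "b", col = 2, pch = 19)
      }
    })
  if (!is.null(res$fst))
    pdf_of("fst_manhattan.pdf",
           manhattan_plot(res$fst$window$chrom, res$fst$window$bp,
                          res$fst$window$fst_win, res$fst$threshold,
                          ylab = "windowed FST"))
  if (!is.null(res$xpehh))
    pdf_of("xpehh_manhattan.pdf",
           manhattan_plot(res$xpehh$chrom, res$xpehh$bp, res$xpehh$z,
                          attr(res$xpehh, "thresholds"), ylab = "XP-EHH z"))
  if (!is.null(res$hapflk))
    pdf_of("hapflk_manhattan.pdf",
           manhattan_plot(res$hapflk$track$chrom, res$hapflk$track$bp,
                          res$hapflk$track$hapflk, NULL, ylab = "hapFLK"))
  invisible(NULL)
}

#' Manhattan-style genome scan plot
#'
#' @param chrom,bp,values per-point chromosome, position and statistic.
#' @param threshold optional horizontal threshold line(s).
#' @param ... passed to [graphics::plot()].
#' @export
manhattan_plot <- function(chrom, bp, values, threshold = NULL, ...) {
  chrom <- as.integer(chrom)
  offs <- c(0, cumsum(tapply(bp, chrom, max)))
  x <- bp + offs[match(chrom, sort(unique(chrom)))]
  graphics::plot(x, values, col = chrom %% 2 + 1, pch = 20, cex = 0.5,
                 xlab = "genome position (bp)", ...)
  if (!is.null(threshold))
    graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(NULL)
}
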