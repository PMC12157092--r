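#' Simulation configuration
#'
#' Describes a two-population forward-in-time Wright-Fisher scenario: an
#' ancestral population of constant size evolves for `burn_in` generations
#' (building up linkage disequilibrium from a linkage-equilibrium start),
#' then splits into two isolated populations, each following its own
#' piecewise-constant size schedule. Optional extras are a hard selective
#' sweep (a new beneficial mutation with additive fitness 1, 1+s, 1+2s) in
#' one population and a final-generations full-sib inbreeding regime.
#'
#' SNPs are array-like: ancestral frequencies are drawn from a configurable
#' spectrum and no new mutations arise during the simulated epoch (except
#' the sweep allele itself).
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp chromosome length in bp.
#' @param n_snp_per_chrom SNPs per chromosome, placed uniformly at random.
#' @param ancestral_ne diploid size of the ancestral population.
#' @param burn_in ancestral generations before the split.
#' @param ne_schedule named list (one entry per population) of two-column
#'   matrices/data.frames `(span, N)`: the population spends `span`
#'   generations at diploid size `N`, in order, after the split.
#' @param sample_size named integer vector: diploids sampled per population
#'   at the end. Defaults c(A = 41, B = 35), the herd sizes of the motivating
#'   two-breed design.
#' @param init_freq list: `dist` = "uniform" (`min`, `max`) or "beta"
#'   (`shape1`, `shape2`, truncated away from 0/1).
#' @param rec_rate recombination rate in Morgans per bp (default 1e-8,
#'   i.e. 1 cM/Mb).
#' @param sweep `NULL`, or list(pop, chrom, bp, s, start_generation,
#'   condition_on_sweep = TRUE, min_final_freq = 0.95, max_retries = 100):
#'   a new beneficial mutation injected as a single copy in `pop` at the
#'   closest SNP to (`chrom`, `bp`) — that SNP is made ancestrally
#'   monomorphic — `start_generation` generations after the split.
#' @param inbreeding `NULL`, or list(pop, fraction, generations): in the last
#'   `generations` generations of `pop`, matings are organised into couples
#'   and the stated fraction of couples are full-sib pairs from the previous
#'   generation (where available).
#' @param track_ibd track founder-allele ancestry labels so that realized
#'   autozygosity can be reported (default TRUE; adds ~60% runtime).
#' @param seed integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2L, chrom_length_bp = 5e7,
                       n_snp_per_chrom = 2000L,
                       ancestral_ne = 100L, burn_in = 100L,
                       ne_schedule = list(A = cbind(span = 100, N = 100),
                                          B = cbind(span = 100, N = 100)),
                       sample_size = c(A = 41L, B = 35L),
                       init_freq = list(dist = "uniform", min = 0.05, max = 0.95),
                       rec_rate = 1e-8,
                       sweep = NULL, inbreeding = NULL,
                       track_ibd = TRUE, seed = 1L) {
  stopifnot(ancestral_ne >= 2, n_chrom >= 1, n_snp_per_chrom >= 1)
  stopifnot(length(ne_schedule) == 2, length(sample_size) == 2)
  if (is.null(names(ne_schedule))) names(ne_schedule) <- c("A", "B")
  if (is.null(names(sample_size))) names(sample_size) <- names(ne_schedule)
  ne_schedule <- lapply(ne_schedule, function(s) {
    s <- as.matrix(s)
    colnames(s) <- c("span", "N")
    stopifnot(all(s[, "span"] >= 0), all(s[, "N"] >= 2))
    s
  })
  if (!is.null(sweep)) {
    stopifnot(sweep$s >= 0, sweep$s <= 1, sweep$pop %in% names(ne_schedule))
    sweep <- utils::modifyList(list(start_generation = 0L,
                                    condition_on_sweep = TRUE,
                                    min_final_freq = 0.95,
                                    max_retries = 100L), sweep)
  }
  if (!is.null(inbreeding))
    stopifnot(inbreeding$fraction >= 0, inbreeding$fraction <= 1,
              inbreeding$pop %in% names(ne_schedule))
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_length_bp = as.numeric(chrom_length_bp),
                 n_snp_per_chrom = as.integer(n_snp_per_chrom),
                 ancestral_ne = as.integer(ancestral_ne),
                 burn_in = as.integer(burn_in),
                 ne_schedule = ne_schedule,
                 sample_size = sample_size,
                 init_freq = init_freq, rec_rate = rec_rate,
                 sweep = sweep, inbreeding = inbreeding,
                 track_ibd = isTRUE(track_ibd), seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_chrom, " chrom x ",
      format(x$chrom_length_bp, big.mark = ","), " bp x ",
      x$n_snp_per_chrom, " SNPs\n", sep = "")
  cat("  ancestral Ne ", x$ancestral_ne, ", burn-in ", x$burn_in,
      " generations\n", sep = "")
  for (p in names(x$ne_schedule))
    cat("  pop ", p, ": ", paste(sprintf("%dg@N=%d", x$ne_schedule[[p]][, 1],
                                         x$ne_schedule[[p]][, 2]), collapse = ", "),
        ", sample ", x$sample_size[[p]], "\n", sep = "")
  if (!is.null(x$sweep))
    cat(sprintf("  sweep: pop %s chrom %d bp %g s=%g\n", x$sweep$pop,
                x$sweep$chrom, x$sweep$bp, x$sweep$s))
  if (!is.null(x$inbreeding))
    cat(sprintf("  inbreeding: pop %s fraction %g last %d generations\n",
                x$inbreeding$pop, x$inbreeding$fraction, x$inbreeding$generations))
  invisible(x)
}

# gametes for a whole offspring generation are assembled in compiled code
# (see src/wf.cpp); parent choice, selection and the mating system stay in R

# advance a population one generation; state = list(H, L, fam);
# haplotype/label matrices are SNPs x (2 * individuals)
.next_generation <- function(state, N_off, geno, s_coef = 0, sweep_col = NA,
                             family_mode = FALSE, sib_fraction = 0) {
  H <- state$H
  N_par <- ncol(H) %/% 2L
  w <- rep(1, N_par)
  if (!is.na(sweep_col) && s_coef > 0) {
    dos <- H[sweep_col, seq(1L, 2L * N_par, 2L)] +
           H[sweep_col, seq(2L, 2L * N_par, 2L)]
    w <- 1 + s_coef * dos
  }
  fam <- rep(NA_integer_, N_off)

  if (family_mode) {
    n_couples <- max(1L, N_off %/% 2L)
    fathers <- integer(n_couples); mothers <- integer(n_couples)
    sib_groups <- NULL
    if (sib_fraction > 0 && !is.null(state$fam) && !all(is.na(state$fam))) {
      tf <- table(state$fam[!is.na(state$fam)])
      sib_groups <- as.integer(names(tf)[tf >= 2L])
    }
    for (cpl in seq_len(n_couples)) {
      use_sibs <- !is.null(sib_groups) && length(sib_groups) > 0 &&
        stats::runif(1) < sib_fraction
      if (use_sibs) {
        g <- sib_groups[sample.int(length(sib_groups), 1L)]
        members <- which(state$fam == g)
        pick <- members[sample.int(length(members), 2L)]
      } else {
        pick <- sample.int(N_par, 2L, prob = w)
        while (pick[1] == pick[2]) pick <- sample.int(N_par, 2L, prob = w)
      }
      fathers[cpl] <- pick[1]; mothers[cpl] <- pick[2]
    }
    cpl_of <- sample.int(n_couples, N_off, replace = TRUE)
    fam <- cpl_of
    pa <- fathers[cpl_of]; ma <- mothers[cpl_of]
  } else {
    pa <- sample.int(N_par, N_off, replace = TRUE, prob = w)
    ma <- sample.int(N_par, N_off, replace = TRUE, prob = w)
    clash <- pa == ma
    while (any(clash)) {
      ma[clash] <- sample.int(N_par, sum(clash), replace = TRUE, prob = w)
      clash <- pa == ma
    }
  }

  parents <- as.integer(as.vector(rbind(pa, ma)))
  kids <- .Call(`_flockscan_wf_children`, H, state$L, parents,
                geno$bp_all, geno$chrom_off, geno$chrom_size,
                geno$len, geno$morgans)
  list(H = kids$H, L = kids$L, fam = fam)
}

#' Run a Wright-Fisher forward simulation
#'
#' Discrete non-overlapping generations, random union of gametes from two
#' distinct parents, per-gamete recombination as Poisson crossovers at the
#' configured rate, populations fully isolated after the split. Deterministic
#' under the config seed. If the sweep is conditioned and the beneficial
#' allele is lost (or fails to reach `min_final_freq`), the post-sweep phase
#' of the selected population is re-run up to `max_retries` times before
#' erroring.
#'
#' @param config a [sim_config()].
#' @return list with elements `gm` (a [genotype_matrix()] of the sampled
#'   individuals), `panel` (the matching phased [haplotype_panel()]) and
#'   `truth` (list: `ne` data.frame of realized sizes per generation per
#'   population, `sweep` final beneficial-allele frequencies and locus, and
#'   `autozygosity` per sampled individual when tracked).
#' @export
sim_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nc <- config$n_chrom; mpc <- config$n_snp_per_chrom
  m <- nc * mpc
  bp_list <- lapply(seq_len(nc), function(i)
    sort(sample.int(config$chrom_length_bp, mpc)))
  geno <- list(bp_all = as.numeric(unlist(bp_list)),
               chrom_off = as.integer((seq_len(nc) - 1L) * mpc),
               chrom_size = rep(as.integer(mpc), nc),
               len = as.numeric(rep(config$chrom_length_bp, nc)),
               morgans = as.numeric(rep(config$chrom_length_bp * config$rec_rate, nc)))
  snps <- data.frame(id = sprintf("snp%d_%d", rep(seq_len(nc), each = mpc),
                                  unlist(lapply(bp_list, seq_along))),
                     chrom = rep(seq_len(nc), each = mpc),
                     bp = unlist(bp_list),
                     allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)

  fr <- config$init_freq
  p0 <- if (identical(fr$dist, "beta")) {
    pmin(pmax(stats::rbeta(m, fr$shape1, fr$shape2), 0.01), 0.99)
  } else stats::runif(m, fr$min, fr$max)

  sweep <- config$sweep
  sweep_col <- NA_integer_
  if (!is.null(sweep)) {
    cand <- which(snps$chrom == sweep$chrom)
    if (!length(cand)) stop("sweep chromosome has no SNPs")
    sweep_col <- cand[which.min(abs(snps$bp[cand] - sweep$bp))]
    p0[sweep_col] <- 0   # new mutation: ancestrally monomorphic
  }

  N0 <- config$ancestral_ne
  # one haplotype per column (SNPs in rows): column-major access keeps the
  # per-gamete copies contiguous
  H <- matrix(stats::rbinom(2L * N0 * m, 1L, p0), m, 2L * N0)
  storage.mode(H) <- "integer"
  L <- if (config$track_ibd)
    matrix(rep(seq_len(2L * N0), each = m), m, 2L * N0) else NULL
  if (!is.null(L)) storage.mode(L) <- "integer"
  anc <- list(H = H, L = L, fam = NULL)

  for (g in seq_len(config$burn_in))
    anc <- .next_generation(anc, N0, geno)

  pops <- names(config$ne_schedule)
  ne_truth <- NULL
  states <- list()
  final_freq <- c()

  for (pn in pops) {
    sched <- config$ne_schedule[[pn]]
    spans <- rep(sched[, "N"], times = sched[, "span"])
    total_g <- length(spans)
    inb <- config$inbreeding
    inb_start <- if (!is.null(inb) && inb$pop == pn)
      total_g - inb$generations + 1L else Inf
    has_sweep <- !is.null(sweep) && sweep$pop == pn

    run_once <- function() {
      st <- anc
      for (g in seq_len(total_g)) {
        if (has_sweep && g == sweep$start_generation + 1L) {
          carrier <- sample.int(ncol(st$H), 1L)
          st$H[sweep_col, carrier] <- 1L
        }
        s_now <- if (has_sweep && g > sweep$start_generation) sweep$s else 0
        fam_mode <- g >= inb_start
        st <- .next_generation(st, spans[g], geno, s_coef = s_now,
                               sweep_col = if (s_now > 0) sweep_col else NA,
                               family_mode = fam_mode,
                               sib_fraction = if (fam_mode) inb$fraction else 0)
        if (has_sweep && g > sweep$start_generation && sweep$condition_on_sweep &&
            sum(st$H[sweep_col, ]) == 0L)
          return(NULL)  # allele lost: abort attempt early
      }
      st
    }

    st <- NULL
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      st <- run_once()
      ok <- !is.null(st)
      if (ok && has_sweep && sweep$condition_on_sweep)
        ok <- mean(st$H[sweep_col, ]) >= sweep$min_final_freq
      if (ok || !has_sweep || !sweep$condition_on_sweep) break
      if (attempts >= sweep$max_retries)
        stop("sweep allele not established after ", attempts, " attempts")
    }
    states[[pn]] <- st
    if (total_g > 0L)
      ne_truth <- rbind(ne_truth,
                        data.frame(pop = pn, generation = seq_len(total_g),
                                   gens_ago = rev(seq_len(total_g)) - 1L,
                                   N = spans, stringsAsFactors = FALSE))
    if (!is.null(sweep))
      final_freq[pn] <- mean(states[[pn]]$H[sweep_col, ])
  }

  # sample individuals (transpose back to haplotypes-in-rows for the panel)
  hap <- NULL; lab <- NULL; iid <- c(); popl <- c()
  for (pn in pops) {
    st <- states[[pn]]
    Np <- ncol(st$H) %/% 2L
    ns <- config$sample_size[[pn]]
    if (ns > Np) stop("sample size exceeds population size for ", pn)
    pick <- sort(sample.int(Np, ns))
    cols <- as.vector(rbind(2L * pick - 1L, 2L * pick))
    hap <- rbind(hap, t(st$H[, cols, drop = FALSE]))
    if (!is.null(st$L)) lab <- rbind(lab, t(st$L[, cols, drop = FALSE]))
    iid <- c(iid, sprintf("%s%03d", pn, seq_len(ns)))
    popl <- c(popl, rep(pn, ns))
  }
  dosage <- hap[seq(1L, nrow(hap), 2L), , drop = FALSE] +
            hap[seq(2L, nrow(hap), 2L), , drop = FALSE]
  gm <- genotype_matrix(dosage, snps,
                        data.frame(iid = iid, pop = popl, stringsAsFactors = FALSE))
  # genotype_matrix() sorts SNPs; positions were generated sorted already
  panel <- haplotype_panel(hap, gm)

  autoz <- NULL
  if (!is.null(lab)) {
    o <- seq(1L, nrow(lab), 2L)
    autoz <- data.frame(iid = iid, pop = popl,
                        autozygosity = rowMeans(lab[o, , drop = FALSE] ==
                                                lab[o + 1L, , drop = FALSE]),
                        stringsAsFactors = FALSE)
  }
  truth <- list(ne = ne_truth,
                sweep = if (is.null(sweep)) NULL else
                  list(chrom = snps$chrom[sweep_col], bp = snps$bp[sweep_col],
                       snp_col = sweep_col, final_freq = final_freq),
                autozygosity = autoz)
  list(gm = gm, panel = panel, truth = truth)
}

#' Mask genotypes at random
#'
#' Each dosage is independently set to missing with probability `rate`.
#'
#' @param gm a [genotype_matrix()].
#' @param rate missingness probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return A [genotype_matrix()] with missing entries.
#' @export
add_missingness <- function(gm, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(gm)
  withr_seed(seed, {
    mask <- matrix(stats::runif(length(gm$dosage)) < rate, nrow(gm$dosage))
    gm$dosage[mask] <- NA_integer_
  })
  gm
}
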