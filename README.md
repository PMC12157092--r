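# flockscan

Runs of homozygosity, effective population size, and selection signatures
from two-population SNP-array genotypes — with a Wright–Fisher simulator
that makes every estimator testable against known truth.

`flockscan` is aimed at population geneticists working with livestock (or
any diploid species) genotyped on medium-density SNP chips, two labelled
populations at a time. It reimplements the standard genome-scan toolchain
as one coherent, seeded, fully scriptable R package:

* **I/O** — PLINK text PED/MAP reading and writing, plain-text phased
  haplotype tables, BED region export.
* **QC** — call-rate filter (0.95), unplaced/non-autosomal removal, pooled
  MAF filter (0.02), exact per-population Hardy–Weinberg tests (α = 10⁻⁶),
  naive Hardy–Weinberg imputation; an auditable per-stage report.
* **ROH / F_ROH** — segment-level detection of runs of homozygosity
  (≤1 heterozygote and ≤2 missing in the interior, ≥40 SNPs, ≥1 SNP/100 kb,
  gaps ≤250 kb, ≥1 Mb), the Lencz minimum-SNP rule
  `l = log(α/(n_s·n_i))/log(1−h̄)`, length-class summaries, chromosome
  coverage, and `F_ROH = ΣL_ROH / L_AUTO`.
* **Ne trajectories** — binned LD decay inverted through
  `N_t = (4c)⁻¹(E[r²_adj|c]⁻¹ − α)`, with `t = (2c)⁻¹` generations ago.
* **Selection scans** — per-SNP Weir–Cockerham θ̂ with Gaussian-kernel
  smoothing, 5-SNP windowed means and top-0.1% calling; XP-EHH from phased
  haplotypes (shared combined-sample truncation at EHH < 0.05, standardized,
  two-tailed 0.1%); FLK and hapFLK (Reynolds distance, two-population
  kinship, K=2 haplotype-cluster EM averaged over `nfit` fits, scaled-χ²
  null, BH q < 0.01).
* **Regions** — per-method candidate regions (500 kb merge), ≥2-method
  consensus (500 kb flank), offline gene-interval annotation.
* **PCA** — GRM-standardized genotype PCA with variance shares.
* **Simulator** — forward Wright–Fisher with recombination, two-population
  splits, per-epoch sizes, hard sweeps (conditioned on establishment),
  final-generation full-sib inbreeding, and exact tracked autozygosity.

## A worked example

Simulate two diverged populations with a hard sweep in population A, run
QC, and scan:

```r
library(flockscan)

cfg <- sim_config(n_chrom = 2, chrom_length_bp = 5e7, n_snp_per_chrom = 2500,
                  ancestral_ne = 600, burn_in = 60,
                  ne_schedule = list(A = cbind(span = 155, N = 600),
                                     B = cbind(span = 155, N = 600)),
                  sample_size = c(A = 41, B = 35),
                  sweep = list(pop = "A", chrom = 1, bp = 2.5e7, s = 0.1),
                  track_ibd = FALSE, seed = 9101)
sim <- sim_population(cfg)
sim$gm
#> <genotype_matrix> 76 individuals x 5000 SNPs
#>   populations: A (41), B (35)
#>   chromosomes: 1 2
#>   missingness: 0.000%

fs <- fst_scan(sim$gm)
fs
#> <fst_scan> 5000 SNPs, 1000 windows (smoothed -> windowed)
#>   threshold (p=0.999): 0.5045; 1 windows flagged
fs$window[fs$window$flag, c("chrom", "bp", "fst_win")]
#>     chrom       bp   fst_win
#> 250     1 25040951 0.5293017
```

The one flagged window sits on top of the simulated sweep (its beneficial
mutation landed at 25,011,656 bp): the windowed Weir–Cockerham F_ST there
(0.53) exceeds the genome-wide 99.9th percentile (0.50). The same run continues into the haplotype scans and the
consensus table:

```r
xp <- xpehh_scan(sim$panel)        # upper tail = selection in A
hf <- hapflk_scan(sim$gm, sim$panel, nfit = 5, seed = 1)
regions <- consensus_regions(rbind(
  merge_flagged_snps(fs$window$flag[match(fs$snp$window, fs$window$window)],
                     fs$snp, method = "FST", stat = "smoothed"),
  merge_flagged_snps(xp$flag_a | xp$flag_b, xp, method = "XPEHH", stat = "z"),
  merge_flagged_snps(hf$track$flag, hf$track, method = "HAPFLK",
                     stat = "hapflk")))
```

`run_pipeline(pipeline_config(...), "out/")` wires all stages together and
writes every table as TSV, deterministically under one root seed;
`inst/scripts/flockscan.R` is a command-line wrapper around it.

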