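---
title: "Models and methods behind flockscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flockscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

flockscan analyses diploid SNP-array genotypes from two labelled
populations — the motivating setting is a pair of livestock breeds genotyped
on a ~50K ovine chip — and answers three families of questions: how much
autozygosity do the genomes carry (runs of homozygosity and F~ROH~), how has
effective population size changed over time (LD decay), and which genomic
regions show evidence of recent positive selection (windowed F~ST~, XP-EHH,
FLK/hapFLK, and their consensus). A forward-in-time Wright–Fisher simulator
with tracked ancestry provides data with known truth, so every estimator in
the package is validated against either an exact oracle or the generative
model itself. This vignette records the models, the defaults, and the design
choices that were genuinely open.

## Genotype containers and quality control

The central object is a `genotype_matrix`: an individuals × SNPs dosage
table (0/1/2/NA counts of `allele_b`) with a sorted SNP map and population
labels. Phased data ride along as a `haplotype_panel` whose haplotype pairs
must sum to the dosages — an invariant checked on construction, which
catches phase/genotype mismatches at the door.

Allele polarity is fixed at load time: `allele_b` is the minor allele across
all individuals, ties broken toward the lexicographically greater allele.
Every downstream statistic is polarity-invariant (F~ST~, FLK and r² are
symmetric in allele relabelling; the EHH computation pools haplotypes rather
than partitioning by an ancestral allele), so this convention only needs to
be consistent, not biologically "correct". An ancestral-allele annotation is
therefore accepted but deliberately ignored.

QC applies, in a fixed order: call-rate filtering at 0.95 (individuals
first, then SNPs — the order the major toolkits use; both counts are
reported so the choice is auditable), removal of unplaced and non-autosomal
markers (autosome codes 1–26 by the ovine convention), a pooled MAF filter
at 0.02 (strict inequality: a SNP exactly at the threshold survives), and an
exact Hardy–Weinberg test at α = 10⁻⁶ applied within each population
separately — a SNP failing in *either* population is removed, since
within-breed disequilibrium at that magnitude is almost always a genotyping
artefact. The HWE test enumerates all heterozygote counts compatible with
the observed allele counts and sums the probabilities of configurations no
more probable than the observed one (no mid-p correction). Full enumeration
is exact for the sample sizes arrays are used at, and exactness is what lets
the test be verified against rational-arithmetic oracles.

Missing genotypes can be imputed by drawing from Hardy–Weinberg proportions
at the population-specific allele frequency. This is deliberately LD-free:
it is plumbing that lets complete-data methods run, not a reconstruction of
haplotypes, and the scientific validation in the test-suite always uses
complete simulated data. Phased analyses (XP-EHH, hapFLK) expect phased
input from the simulator or an external phaser; if QC-plus-imputation
changes dosages, the stale panel is dropped rather than silently reused.

## Runs of homozygosity

A run of homozygosity is a maximal stretch of SNPs in one individual
satisfying all of: at most 1 heterozygous and at most 2 missing calls in its
interior; at least 40 SNPs; at least one SNP per 100 kb on the whole segment
(`length/n ≤ 100 kb`, the PLINK-style whole-segment density rule); no
inter-SNP gap above 250 kb; and at least 1 Mb long (the lower edge of the
smallest reported length class). Segment ends must be homozygous non-missing
calls — without that rule the heterozygote budget would absorb a flanking
heterozygote and every run would be padded by one SNP on each side.

The common sliding-window screening is treated as an implementation device,
not as part of the definition: the scanner works directly at segment level,
taking for each qualifying start the longest valid end and continuing after
it. This greedy scan provably returns exactly the maximal non-overlapping
qualifying segments (leftmost-first), and the test suite checks it against
an exhaustive oracle that enumerates all O(m²) sub-intervals on hundreds of
random fixtures.

The minimum SNP count doubles as an output of the Lencz false-positive rule
`l = log(alpha/(n_s·n_i)) / log(1 − mean_het)`; with chip-scale inputs
(≈44k SNPs, ≈40 individuals, α = 0.05, mean heterozygosity 0.35) it gives
l ≈ 40.4, which is why 40 is the default minimum.

F~ROH~ divides each individual's summed ROH length by the autosomal length
covered by SNPs (configurable; the chip-scale constant for sheep is
2.463 Gb, the package default is the summed per-chromosome SNP span).
Length-class summaries use the classes [1,5), [5,10), [10,15), [15,20),
[20,∞) Mb, summing per individual within class and averaging per breed.

## Effective population size from LD decay

For SNP pairs at recombination distance c, drift-recombination balance
gives E[r²~adj~] ≈ 1/(α + 4Nc), and each distance bin informs a time point
t = 1/(2c) generations ago. The package inverts this directly:
N_t = (1/(4c)) · (1/mean(r²~adj~) − α) per bin, with c mapped from the mean
pair distance in the bin. This inversion is exact by construction — a test
feeds bins built from the forward relation and requires the estimator to
return N to machine precision — so all empirical error comes from the LD
measurement, not the algebra.

Defaults and the reasoning behind them:

* **r²** is the squared Pearson correlation of dosages (unphased) or of
  haplotype alleles (phased), pairwise-complete over missing data. SNPs are
  pre-filtered at MAF 0.05 — low-MAF pairs have noisy, upward-biased r².
* **Sample-size adjustment**: subtract 1/n~hap~ (phased) or 1/(2n~ind~)
  (unphased). Negative adjusted values are kept; flooring at zero would
  bias bin means upward. The unphased constant undercorrects composite
  genotype r² (whose independence floor is ≈ 1/(n−1) in individuals); the
  mode is config-exposed, recorded in the trajectory metadata, and the
  package's own validation uses phased mode where floor and correction
  agree.
* **Mapping**: linear 1 cM/Mb by default; Haldane and a hyperbolic map
  c = d/(1+2d) are offered. No genetic map is assumed beyond the cM/Mb
  constant, which is configurable.
* **α (mutation adjustment)**: 2.2 by the SNeP convention for real data;
  1.0 for mutation-free data. The package simulator introduces no new
  mutations, so all simulation-based validation runs with α = 1.
* **Bins**: 13 geometric bins from 50 kb to 25 Mb, at least 50 pairs per
  bin; under-filled or algebraically invalid bins (1/mean ≤ α) are flagged
  `valid = FALSE` rather than dropped, so trajectories keep their shape.

Simulation recovery at constant N = 100 (20 replicates, two 50 Mb
chromosomes of 1200 SNPs each, 250 + 50 generations) lands within ~15% at
mid-range bins (0.8–12 Mb; the asserted tolerance is ±30%); distal bins
reflect the linkage-equilibrium initialisation rather than drift
equilibrium and are not asserted.

## Weir–Cockerham F~ST~ scan

Per SNP, the two-population Weir–Cockerham variance-components estimator
θ̂ = a/(a+b+c) is computed from sample sizes, allele frequencies and
heterozygote proportions. Negative estimates are retained (truncation
biases window means); SNPs monomorphic in both populations are flagged and
excluded from thresholds. The implementation from per-population summaries
is cross-checked, to 10⁻¹², against an independently coded nested-ANOVA
oracle that works from raw dosages.

The scan then (1) smooths raw θ̂ along each chromosome with Nadaraya–Watson
local-constant regression under a Gaussian kernel, (2) averages each block
of 5 adjacent SNPs of the smoothed track into a "windowed F~ST~"
(non-overlapping blocks, trailing remainder kept), and (3) flags windows
strictly above the empirical 99.9th percentile of windowed values. Open
choices and how they were fixed:

* the percentile is taken over *windowed* values (the plotted track), with
  raw and smoothed tracks also recorded;
* the default bandwidth is 5× the median inter-SNP spacing per chromosome
  (logged in the output). A global density-estimation rule of thumb was
  rejected: on a 50 Mb axis it yields multi-megabase bandwidths that
  flatten selection peaks, which live at the 0.1–1 Mb scale of
  hitchhiking. A plug-in local-bandwidth smoother would also be reasonable;
  the spacing rule is transparent and scale-appropriate;
* windows are computed from the smoothed track by default
  (`window_input = "raw"` is available and recorded).

## XP-EHH

EHH from a core SNP is the probability that two random haplotypes are
identical at every SNP from the core out to a distance; the package pools
all haplotypes of a population (no ancestral-allele partition), which makes
the statistic polarity-free. The curve starts at 1 at distance zero, the
core allele joins the prefix from the first flanking SNP, and monotone
non-increase is asserted on every curve. iHH integrates the curve
(trapezoid, physical distance) from the core to the truncation point —
the first SNP at which the EHH of the *combined* two-population sample
drops below 0.05 — shared by both populations so the ratio compares like
with like. XP-EHH = ln(iHH_A/iHH_B); positive means longer homozygosity
(recent selection) in A. Scores are standardized to mean 0, sd 1, and the
upper and lower 0.1% tails are flagged separately, upper for A, lower
for B.

Cores within 1 Mb of a chromosome end, cores whose combined EHH never
decays below the threshold (the integral would be boundary-censored), and
cores with a zero iHH are excluded from standardization and flagging, with
the exclusion recorded per core. Integration is over physical distance; a
constant per-bp scale cancels in the log ratio. The compiled scan is
checked against a pure-R reference arm integration, and the R EHH against a
string-hashing oracle.

## FLK and hapFLK

The Reynolds coancestry distance D between the two populations is the
classical ratio-of-sums estimator (fixed difference at every SNP gives 1;
identical frequencies give 0). With only two populations and no outgroup
the two branch lengths cannot be separated, and the estimator measures the
*average* per-population drift since the split. The kinship matrix is
therefore taken as F = diag(D, D): under the drift model
Var(p_A − p_B) = 2·F̄·p₀(1−p₀), and the FLK quadratic form
(p − p̂₀)ᵀ(p₀(1−p₀)F)⁻¹(p − p̂₀) with GLS mean p̂₀ is χ²₁ exactly when the
diagonal equals the average drift F̄ ≈ D. Halving the diagonal (a "midpoint
rooting" reading) doubles the statistic's null mean; the package keeps the
calibrated form, and neutral simulations reproduce a mean FLK within a few
percent of 1. SNPs with p̂₀ of 0 or 1 are flagged and excluded.

hapFLK replaces allele frequencies with local haplotype-cluster
frequencies. The LD model is a fastPHASE-style hidden Markov model over
phased haplotypes: K clusters (default 2) as hidden states, per-SNP
per-cluster allele frequencies as emissions, and per-interval switch rates
with per-SNP jump-destination weights as transitions. EM with exact
M-steps for all three parameter sets keeps the log-likelihood monotone
(asserted in tests); fits stop at 50 iterations or relative tolerance
10⁻⁶, are initialized from perturbed pooled frequencies with a uniform
switch rate of 0.05, and are fully seeded. Per fit, population-level
cluster frequencies come from posterior memberships and enter the same
kinship-scaled quadratic form on the K−1 free frequencies; the hapFLK value
is the mean over `nfit` independent EM fits (default 20, matching common
practice — averaging over restarts integrates out label-switching and
local optima).

P-values come from a null fitted to the genome-wide hapFLK distribution:
a scaled χ² whose scale and degrees of freedom minimize the squared
distance between empirical and theoretical quantiles on the central 90%
(probabilities 0.05–0.95, so selected outliers cannot distort the null).
The exact normalization used by the original helper scripts is not
published; this robust quantile fit is a documented stand-in validated by
its FDR behaviour on neutral simulations. Benjamini–Hochberg q-values are
thresholded at 0.01.

## PCA

Dosages are centred by 2p̂ and scaled by √(2p̂(1−p̂)) (the GRM convention;
monomorphic SNPs dropped), and scores are the leading left singular vectors
scaled by the singular values. Each component's sign is fixed by making its
largest-magnitude SNP loading positive, so results are reproducible to the
byte. Variance proportions are eigenvalue shares of the full spectrum.

## Candidate regions and consensus

Per method, flagged SNPs (or windows mapped back to their member SNPs) are
merged into regions when consecutive flagged positions lie within 500 kb;
region bounds are the member min/max positions, 1-based inclusive
(conversion to BED's 0-based half-open convention happens only in the BED
writer). Regions from different methods whose 500 kb-expanded intervals
intersect are grouped transitively, and groups supported by at least two
of the three methods become consensus regions. Gene annotation is plain
interval intersection of flank-expanded regions against a user-supplied
gene table (data.frame, BED or GFF3 via rtracklayer) — no online database
access, and no enrichment statistics: ontology databases version too fast
for a reproducible test to assert anything about them.

## The simulator: what it emulates, and what it does not

`sim_population()` is a discrete-generation diploid Wright–Fisher model:
random union of gametes from two distinct parents, per-gamete recombination
as Poisson crossovers on a uniform map, an ancestral burn-in that builds LD
from a linkage-equilibrium start, a clean two-population split with no
subsequent migration, piecewise-constant population sizes, an optional hard
sweep (a new beneficial mutation at a pre-chosen, ancestrally monomorphic
site; additive fitness 1, 1+s, 1+2s; optionally conditioned on reaching
near-fixation, with early abort and retry on loss), and an optional
final-generations full-sib mating regime implemented mechanistically:
matings are organised into couples and the configured fraction of couples
are full-sib pairs, which yields the pedigree expectation F ≈ 0.25 after
one generation. Autozygosity is tracked exactly by founder-allele labels
that recombine alongside the alleles.

SNPs are array-like: ancestral frequencies drawn from a configurable
spectrum (uniform 0.05–0.95 by default, emulating ascertained chip SNPs)
and no new mutation during the simulated epoch. Consequences worth keeping
in mind when reading test results: allele-frequency spectra are flatter
than real chip data; there is no genotyping error, no LD-ascertainment
structure, no sex chromosomes, and no migration or admixture. Passing tests
demonstrate that the estimators recover the truth of *this* generative
model at desk scale — they do not certify behaviour under array
ascertainment bias or cryptic relatedness.

Default sample sizes are 41 and 35 diploids — the two-breed design the
package is modelled on. The default desk scale (2 chromosomes × 50 Mb ×
2000–3000 SNPs, N ≤ 200, ≤ 300 generations) runs in seconds to tens of
seconds per replicate on one CPU. The validation suite uses: N = 100,
250 + 50 generations, 2 × 1200 SNPs for Ne recovery (20 replicates);
N = 100, 100 + 50 generations, 1500 SNPs for FLK calibration
(20 replicates); and for sweep power N = 600 per population, 60 burn-in +
155 post-split generations, s = 0.1 from a new mutation arising at the
split, conditioned on final frequency ≥ 0.95, 2 × 2500 SNPs. The hapFLK
elevation check — an on-locus versus off-locus mean comparison — runs on
the sweep chromosome with 3 EM fits of at most 15 iterations (the
statistic is defined for any number of fits; 20 remains the pipeline
default). The population size for the sweep
study was chosen because drift background F~ST~ scales like ln(2N)/(sN)
while the sweep's own contrast does not depend on N: at small N, drift
outliers dominate the genome-wide top 0.1% and *no* method should be
expected to rank a sweep above them. Detection is scored within ±2.5 Mb
of the locus — the hitchhiking footprint at these parameters; XP-EHH in
particular peaks on the shoulders of a fixed sweep rather than at the
fixed site itself.

## Numerical choices and degenerate inputs

* HWE: log-factorial enumeration; probability ties in the two-sided sum are
  compared with a 10⁻⁹ relative guard.
* Zero-variance or monomorphic SNPs: skipped in r² pairs, flagged in
  F~ST~/FLK, dropped in PCA standardization.
* Identical panels give raw XP-EHH exactly 0 with sd 0; standardization
  returns all-zero z rather than NaN.
* All statistics that threshold on empirical percentiles warn below 1000
  values (the 0.1% tail is then dominated by single order statistics).
* All randomness (simulator, imputation, EM initialisation) flows from
  explicit seeds; the pipeline derives stage seeds from one root seed, and
  a rerun is byte-identical on every table.

## Known limitations

Two populations only (FLK/hapFLK close over the no-outgroup two-leaf case;
the general kinship tree is out of scope); no LD-aware imputation or
phasing of real data; LD-based Ne is biased at the most recent bins when
sample sizes are small, and the genotype-mode sample-size correction is
approximate; XP-EHH integrates physical, not genetic, distance; hapFLK
p-values depend on a parametric null stand-in. The region annotator
deliberately stops at interval intersection — interpretation of gene
content is the analyst's task.
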