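Package: flockscan
Title: Runs of Homozygosity, Effective Population Size and Selection
    Signatures from SNP-Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for two-population SNP-array studies in
    livestock and other diploid species: PLINK text PED/MAP input and output,
    a genotype quality-control cascade (call rate, chromosome placement,
    minor-allele frequency, per-population exact Hardy-Weinberg tests),
    runs-of-homozygosity detection with the Lencz minimum-SNP rule and
    ROH-based inbreeding coefficients, linkage-disequilibrium-based historical
    effective population size trajectories, three selection-signature scans
    (windowed Weir-Cockerham FST with kernel smoothing, cross-population
    extended haplotype homozygosity XP-EHH, and FLK/hapFLK with a
    haplotype-cluster hidden Markov model), principal-component analysis of
    population structure, candidate-region extraction with cross-method
    consensus, and a forward-in-time Wright-Fisher simulator with tracked
    autozygosity, configurable demography, recent inbreeding and hard
    selective sweeps for validation with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    IRanges,
    rtracklayer,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
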