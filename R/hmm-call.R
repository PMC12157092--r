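# thin .Call bridge to the compiled haplotype-cluster EM
.hmm_cluster_em <- function(hap, K, theta_init, rho_init, max_iter, tol) {
  .Call(`_flockscan_hmm_cluster_em`, hap, K, theta_init, rho_init,
        max_iter, tol)
}
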