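#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Assemble one generation of gametes.
//
// H (and optionally the ancestry-label matrix L) hold one haplotype per
// column, SNPs in rows. `parents` lists, per offspring, the father and
// mother (1-based individual indices into the parent generation), so its
// length is 2 * N_off. For each gamete, crossovers are Poisson on the
// genetic length of each chromosome with a random starting phase; the R
// RNG is used throughout, so results are reproducible under set.seed().
//
// chrom_offset[c] is the 0-based first SNP row of chromosome c,
// chrom_size[c] its SNP count; bp holds all positions, chrom_len_bp and
// morgans the physical and genetic lengths per chromosome.
extern "C" SEXP _flockscan_wf_children(SEXP HSEXP, SEXP LSEXP, SEXP parentsSEXP,
                                       SEXP bpSEXP, SEXP chromOffSEXP,
                                       SEXP chromSizeSEXP, SEXP chromLenSEXP,
                                       SEXP morgansSEXP) {
  BEGIN_RCPP
  IntegerMatrix H(HSEXP);
  const bool hasL = !Rf_isNull(LSEXP);
  IntegerMatrix L = hasL ? IntegerMatrix(LSEXP) : IntegerMatrix(0, 0);
  IntegerVector parents(parentsSEXP);
  NumericVector bp(bpSEXP);
  IntegerVector chromOff(chromOffSEXP), chromSize(chromSizeSEXP);
  NumericVector chromLen(chromLenSEXP), morgans(morgansSEXP);

  const int m = H.nrow();
  const int n_gam = parents.size();
  const int n_chrom = chromOff.size();

  IntegerMatrix newH(m, n_gam);
  IntegerMatrix newL(hasL ? m : 0, hasL ? n_gam : 0);
  std::vector<double> xo;

  GetRNGstate();
  for (int g = 0; g < n_gam; ++g) {
    const int p = parents[g] - 1;
    const int c1 = 2 * p, c2 = 2 * p + 1;
    int* h1 = &H(0, c1);
    int* h2 = &H(0, c2);
    int* out = &newH(0, g);
    int* l1 = hasL ? &L(0, c1) : nullptr;
    int* l2 = hasL ? &L(0, c2) : nullptr;
    int* lout = hasL ? &newL(0, g) : nullptr;

    for (int c = 0; c < n_chrom; ++c) {
      const int off = chromOff[c], sz = chromSize[c];
      int k = static_cast<int>(R::rpois(morgans[c]));
      int phase = unif_rand() < 0.5 ? 0 : 1;
      if (k == 0) {
        const int* src = phase == 0 ? h1 : h2;
        std::copy(src + off, src + off + sz, out + off);
        if (hasL) {
          const int* lsrc = phase == 0 ? l1 : l2;
          std::copy(lsrc + off, lsrc + off + sz, lout + off);
        }
      } else {
        xo.resize(k);
        for (int i = 0; i < k; ++i) xo[i] = unif_rand() * chromLen[c];
        std::sort(xo.begin(), xo.end());
        int xi = 0;
        int cur = phase;
        for (int j = off; j < off + sz; ++j) {
          while (xi < k && bp[j] > xo[xi]) { cur ^= 1; ++xi; }
          out[j] = (cur == 0 ? h1 : h2)[j];
          if (hasL) lout[j] = (cur == 0 ? l1 : l2)[j];
        }
      }
    }
  }
  PutRNGstate();

  return List::create(_["H"] = newH,
                      _["L"] = hasL ? (SEXP) newL : R_NilValue);
  END_RCPP
}
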