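#include <Rcpp.h>
using namespace Rcpp;

// Cross-population EHH scan core.
//
// hap: (nA + nB) x m matrix of 0/1 alleles, population A in the first nA
// rows. For every core SNP, both arms are extended while the EHH of the
// combined sample stays >= trunc; each population's own EHH curve is
// integrated (trapezoid over bp) up to the shared truncation point.
//
// Returns an m x 3 matrix: iHH_A, iHH_B, flag (0 ok, 1 = combined EHH never
// decayed before a chromosome end, 2 = excluded by the edge margin).
extern "C" SEXP _flockscan_xpehh_scan_core(SEXP hapSEXP, SEXP nASEXP,
                                           SEXP bpSEXP, SEXP truncSEXP,
                                           SEXP marginSEXP) {
  BEGIN_RCPP
  IntegerMatrix hap(hapSEXP);
  const int nA = Rcpp::as<int>(nASEXP);
  NumericVector bp(bpSEXP);
  const double trunc = Rcpp::as<double>(truncSEXP);
  const double margin = Rcpp::as<double>(marginSEXP);

  const int n = hap.nrow(), m = hap.ncol();
  const int nB = n - nA;
  const double dP = n * (n - 1.0) / 2.0;
  const double dA = nA * (nA - 1.0) / 2.0;
  const double dB = nB * (nB - 1.0) / 2.0;

  NumericMatrix out(m, 3);
  std::vector<int> g(n), g2(n), remap(2 * (n + 1));
  std::vector<double> cntP(n + 1), cntA(n + 1), cntB(n + 1);

  double lo = bp[0] + margin, hi = bp[m - 1] + 0.0 - margin;

  for (int core = 0; core < m; ++core) {
    if (bp[core] < lo || bp[core] > hi) {
      out(core, 0) = NA_REAL; out(core, 1) = NA_REAL; out(core, 2) = 2;
      continue;
    }
    double ihhA = 0, ihhB = 0;
    bool edge = false;
    for (int dir = 0; dir < 2; ++dir) {
      // distance 0: EHH = 1 for pooled and both subsets
      for (int h = 0; h < n; ++h) g[h] = hap(h, core);
      double eP = 1.0, eA = 1.0, eB = 1.0;
      double prevDist = 0.0;
      int ngroups = 2;
      bool truncated = false;
      int j = core;
      while (true) {
        j += (dir == 0 ? 1 : -1);
        if (j < 0 || j >= m) break;
        // refine groups by the allele at j
        std::fill(remap.begin(), remap.begin() + 2 * (ngroups + 1), -1);
        int next = 0;
        for (int h = 0; h < n; ++h) {
          int key = g[h] * 2 + hap(h, j);
          if (remap[key] < 0) remap[key] = next++;
          g2[h] = remap[key];
        }
        ngroups = next;
        std::fill(cntP.begin(), cntP.begin() + ngroups, 0.0);
        std::fill(cntA.begin(), cntA.begin() + ngroups, 0.0);
        std::fill(cntB.begin(), cntB.begin() + ngroups, 0.0);
        for (int h = 0; h < n; ++h) {
          cntP[g2[h]] += 1.0;
          if (h < nA) cntA[g2[h]] += 1.0; else cntB[g2[h]] += 1.0;
        }
        double sP = 0, sA = 0, sB = 0;
        for (int k = 0; k < ngroups; ++k) {
          sP += cntP[k] * (cntP[k] - 1.0) / 2.0;
          sA += cntA[k] * (cntA[k] - 1.0) / 2.0;
          sB += cntB[k] * (cntB[k] - 1.0) / 2.0;
        }
        double eP2 = sP / dP, eA2 = sA / dA, eB2 = sB / dB;
        double dist = std::abs(bp[j] - bp[core]);
        ihhA += (eA + eA2) / 2.0 * (dist - prevDist);
        ihhB += (eB + eB2) / 2.0 * (dist - prevDist);
        prevDist = dist;
        eP = eP2; eA = eA2; eB = eB2;
        std::swap(g, g2);
        if (eP < trunc) { truncated = true; break; }
      }
      if (!truncated) edge = true;
    }
    out(core, 0) = ihhA;
    out(core, 1) = ihhB;
    out(core, 2) = edge ? 1 : 0;
  }
  return out;
  END_RCPP
}
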