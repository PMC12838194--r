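#include <Rcpp.h>
using namespace Rcpp;

// Pairwise abundance-weighted beta mean nearest taxon distance.
//
// D:    taxon x taxon patristic distance matrix
// F:    sample x taxon weight matrix (relative abundances; 0 = absent)
// perm: 0-based permutation of taxon indices applied to D's labels,
//       so null randomizations (tip shuffles) reuse one kernel.
//
// bMNTD(k,l) = 0.5 * [ sum_{i in k} F(k,i) * min_{j in l} D(i,j)
//                    + sum_{j in l} F(l,j) * min_{i in k} D(i,j) ]
// [[Rcpp::export]]
NumericMatrix bmntd_matrix(NumericMatrix D, NumericMatrix F,
                           IntegerVector perm) {
  const int n = F.nrow();
  const int S = F.ncol();
  if (D.nrow() != S || D.ncol() != S)
    stop("distance matrix does not match taxon count");
  if (perm.size() != S) stop("perm must have one entry per taxon");

  std::vector< std::vector<int> > present(n);
  for (int k = 0; k < n; ++k) {
    for (int s = 0; s < S; ++s) {
      if (F(k, s) > 0) present[k].push_back(s);
    }
  }

  NumericMatrix out(n, n);
  for (int k = 0; k < n; ++k) {
    for (int l = k + 1; l < n; ++l) {
      const std::vector<int>& pk = present[k];
      const std::vector<int>& pl = present[l];
      double t1 = 0.0;
      for (size_t a = 0; a < pk.size(); ++a) {
        const int i = perm[pk[a]];
        double mn = R_PosInf;
        for (size_t b = 0; b < pl.size(); ++b) {
          const double d = D(i, perm[pl[b]]);
          if (d < mn) mn = d;
        }
        t1 += F(k, pk[a]) * mn;
      }
      double t2 = 0.0;
      for (size_t b = 0; b < pl.size(); ++b) {
        const int j = perm[pl[b]];
        double mn = R_PosInf;
        for (size_t a = 0; a < pk.size(); ++a) {
          const double d = D(perm[pk[a]], j);
          if (d < mn) mn = d;
        }
        t2 += F(l, pl[b]) * mn;
      }
      out(k, l) = out(l, k) = 0.5 * (t1 + t2);
    }
  }
  return out;
}
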