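#include <Rcpp.h>
using namespace Rcpp;

// Nearest-taxon distances under a taxon relabeling.
//
// D is the taxa x taxa patristic matrix, `present` a list of 0-based index
// vectors of the taxa present in each sample, and `perm` a 0-based
// permutation of the taxa (tip shuffle; identity gives the observed case).
// Returns M (taxa x samples) with M(i, s) = min over j present in s of
// D(perm[i], perm[j]). betaMNTD then follows from one crossprod with the
// per-sample weight matrix.
// [[Rcpp::export]]
NumericMatrix nearest_taxon_mins(const NumericMatrix& D, const List& present,
                                 const IntegerVector& perm) {
  const int nt = D.nrow();
  const int ns = present.size();
  NumericMatrix M(nt, ns);
  for (int s = 0; s < ns; ++s) {
    IntegerVector pres = present[s];
    const int np = pres.size();
    std::vector<int> pcol(np);
    for (int k = 0; k < np; ++k) pcol[k] = perm[pres[k]];
    for (int i = 0; i < nt; ++i) {
      const double* row = &D(0, 0) + (std::size_t)perm[i]; // column-major
      double m = R_PosInf;
      for (int k = 0; k < np; ++k) {
        double v = row[(std::size_t)pcol[k] * nt];
        if (v < m) m = v;
      }
      M(i, s) = m;
    }
  }
  return M;
}
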