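// Shell accumulation for the pair correlation function.
//
// Given the (symmetric) matrix of pairwise edge distances and the field p,
// accumulates for every r = 0..r_max the outer sum
//   sum_i p_i * (1/n(r,i)) * sum_{j: d(i,j)=r} p_j
// in one pass over the matrix, plus the per-r count of source vertices
// with a nonempty shell.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List tpcf_accum_cpp(NumericMatrix d, NumericVector p, int r_max) {
  const int n = d.nrow();
  NumericVector gnum(r_max + 1);
  IntegerVector nsrc(r_max + 1);
  std::vector<double> ssum(r_max + 1);
  std::vector<int> scnt(r_max + 1);
  for (int i = 0; i < n; ++i) {
    std::fill(ssum.begin(), ssum.end(), 0.0);
    std::fill(scnt.begin(), scnt.end(), 0);
    const double *col = &d(0, i); // symmetric: column i == row i
    for (int j = 0; j < n; ++j) {
      const double dij = col[j];
      if (dij <= r_max) { // Inf (unreachable) fails this test
        const int r = (int)dij;
        ssum[r] += p[j];
        scnt[r] += 1;
      }
    }
    for (int r = 0; r <= r_max; ++r) {
      if (scnt[r] > 0) {
        gnum[r] += p[i] * ssum[r] / scnt[r];
        nsrc[r] += 1;
      }
    }
  }
  return List::create(_["gnum"] = gnum, _["n_sources"] = nsrc);
}
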