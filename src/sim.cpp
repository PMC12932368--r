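#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// All randomness goes through R's RNG (unif_rand / R::rpois) so that results
// are reproducible from set.seed() on any platform. Callers must therefore
// seed from R before invoking these routines.

namespace {

// Sample one gamete from a pair of haplotype columns (h1, h2) of H.
// Crossover count ~ Poisson(chr_len_cM / 100), positions uniform on
// (0, chr_len_cM), no interference (Haldane model), random starting strand.
inline void sample_gamete(const int* h1, const int* h2, const double* pos,
                          int n_loci, double chr_len_cM, int* out,
                          std::vector<double>& cx) {
  int ncx = (int) R::rpois(chr_len_cM / 100.0);
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  if (ncx == 0) {
    const int* src = cur ? h2 : h1;
    std::copy(src, src + n_loci, out);
    return;
  }
  cx.resize(ncx);
  for (int i = 0; i < ncx; ++i) cx[i] = unif_rand() * chr_len_cM;
  std::sort(cx.begin(), cx.end());
  int j = 0;
  for (int l = 0; l < n_loci; ++l) {
    while (j < ncx && cx[j] <= pos[l]) { cur ^= 1; ++j; }
    out[l] = cur ? h2[l] : h1[l];
  }
}

} // namespace

//' @name cpp_gametes
//' @title Sample gametes from pairs of haplotype columns
//' @noRd
// [[Rcpp::export(rng = true)]]
IntegerMatrix cpp_gametes(const IntegerMatrix& H, const NumericVector& pos,
                          double chr_len_cM, const IntegerVector& hap1,
                          const IntegerVector& hap2) {
  const int S = H.nrow();
  const int n = hap1.size();
  if (hap2.size() != n) stop("hap1 and hap2 must have equal length");
  IntegerMatrix out(S, n);
  std::vector<double> cx;
  for (int g = 0; g < n; ++g) {
    int c1 = hap1[g] - 1, c2 = hap2[g] - 1;
    if (c1 < 0 || c2 < 0 || c1 >= H.ncol() || c2 >= H.ncol())
      stop("haplotype index out of range");
    sample_gamete(&H(0, c1), &H(0, c2), &pos[0], S, chr_len_cM, &out(0, g), cx);
  }
  return out;
}

//' @name cpp_burnin
//' @title Wright-Fisher burn-in with recombination and mutation
//' @noRd
// [[Rcpp::export(rng = true)]]
IntegerMatrix cpp_burnin(const IntegerMatrix& H0, const NumericVector& pos,
                         double chr_len_cM, int n_gen, double mut_per_site) {
  const int S = H0.nrow();
  const int n2 = H0.ncol();           // 2N haplotypes
  if (n2 % 2 != 0) stop("haplotype count must be even");
  const int N = n2 / 2;
  IntegerMatrix A = clone(H0), B(S, n2);
  std::vector<double> cx;
  for (int gen = 0; gen < n_gen; ++gen) {
    for (int i = 0; i < N; ++i) {
      int mo = (int)(unif_rand() * N); if (mo == N) mo = N - 1;
      int fa = (int)(unif_rand() * N); if (fa == N) fa = N - 1;
      sample_gamete(&A(0, 2 * mo), &A(0, 2 * mo + 1), &pos[0], S, chr_len_cM,
                    &B(0, 2 * i), cx);
      sample_gamete(&A(0, 2 * fa), &A(0, 2 * fa + 1), &pos[0], S, chr_len_cM,
                    &B(0, 2 * i + 1), cx);
    }
    if (mut_per_site > 0) {
      int nmut = (int) R::rpois(mut_per_site * (double) S * (double) n2);
      for (int m = 0; m < nmut; ++m) {
        int l = (int)(unif_rand() * S); if (l == S) l = S - 1;
        int h = (int)(unif_rand() * n2); if (h == n2) h = n2 - 1;
        B(l, h) ^= 1;
      }
    }
    std::swap(A, B);
  }
  return A;
}
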