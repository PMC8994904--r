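#include <Rcpp.h>
using namespace Rcpp;

// Gamete sampling for a batch of parents.  hap1/hap2 are n x L allele
// matrices (0/1) ordered by the gene map; switch_prob[j] is the
// probability that the source haplotype switches immediately before locus
// j: 0.5 at the first locus of every chromosome (independent assortment,
// uniform start) and the Haldane recombination fraction of the adjacent
// spacing elsewhere.  One gamete per row.
// [[Rcpp::export]]
IntegerMatrix cpp_gametes(const IntegerMatrix& hap1, const IntegerMatrix& hap2,
                          const NumericVector& switch_prob) {
  const int n = hap1.nrow(), L = hap1.ncol();
  if (hap2.nrow() != n || hap2.ncol() != L || switch_prob.size() != L)
    stop("dimension mismatch in cpp_gametes");
  IntegerMatrix out(n, L);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    int state = 0;
    for (int j = 0; j < L; ++j) {
      if (unif_rand() < switch_prob[j]) state = 1 - state;
      out(i, j) = state == 0 ? hap1(i, j) : hap2(i, j);
    }
  }
  return out;
}
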