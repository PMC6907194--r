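#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Haplotypes are stored as a raw matrix with one locus per row and one
// haplotype per column; individual i (0-based) owns columns 2i and 2i+1.
// Loci are ordered by (chromosome, map position); chrom_offset holds the
// 0-based first-locus index of each chromosome plus a terminal sentinel
// equal to the total locus count.

// Drop one gamete per entry of `parent`: recombine the two haplotypes of
// that parent with Poisson(L_Morgan) crossovers per chromosome (no
// interference, independent assortment) and flip each transmitted allele
// with probability mut_rate (recurrent biallelic mutation).
// [[Rcpp::export]]
RawMatrix cpp_drop_gametes(RawMatrix haps, IntegerVector parent,
                           NumericVector pos_morgan, IntegerVector chrom_offset,
                           double mut_rate) {
  const int n_loci = haps.nrow();
  const int n_gam = parent.size();
  const int n_chr = chrom_offset.size() - 1;
  RawMatrix out(n_loci, n_gam);

  std::vector<double> xo; // crossover positions within a chromosome
  for (int g = 0; g < n_gam; ++g) {
    const int p = parent[g];
    const Rbyte *hapA = &haps(0, 2 * p);
    const Rbyte *hapB = &haps(0, 2 * p + 1);
    Rbyte *dst = &out(0, g);
    for (int c = 0; c < n_chr; ++c) {
      const int lo = chrom_offset[c], hi = chrom_offset[c + 1];
      if (hi <= lo) continue;
      const double start = pos_morgan[lo];
      const double len = pos_morgan[hi - 1] - start;
      int cur = (unif_rand() < 0.5) ? 0 : 1; // random start haplotype
      int k = (len > 0.0) ? (int) R::rpois(len) : 0;
      if (k == 0) {
        const Rbyte *src = cur ? hapB : hapA;
        std::copy(src + lo, src + hi, dst + lo);
        continue;
      }
      xo.resize(k);
      for (int j = 0; j < k; ++j) xo[j] = start + unif_rand() * len;
      std::sort(xo.begin(), xo.end());
      int j = 0;
      for (int l = lo; l < hi; ++l) {
        while (j < k && xo[j] < pos_morgan[l]) { cur ^= 1; ++j; }
        dst[l] = cur ? hapB[l] : hapA[l];
      }
    }
    if (mut_rate > 0.0) {
      int nmut = (int) R::rbinom((double) n_loci, mut_rate);
      for (int j = 0; j < nmut; ++j) {
        int l = (int) (unif_rand() * n_loci);
        if (l >= n_loci) l = n_loci - 1;
        dst[l] ^= 1;
      }
    }
  }
  return out;
}

// Allele counts (0/1/2) per individual at a subset of loci.
// loci: 0-based row indices into haps; result is individuals x loci.
// [[Rcpp::export]]
IntegerMatrix cpp_allele_counts(RawMatrix haps, IntegerVector loci) {
  const int n_ind = haps.ncol() / 2;
  const int m = loci.size();
  IntegerMatrix out(n_ind, m);
  for (int j = 0; j < m; ++j) {
    const int l = loci[j];
    for (int i = 0; i < n_ind; ++i)
      out(i, j) = (int) haps(l, 2 * i) + (int) haps(l, 2 * i + 1);
  }
  return out;
}
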