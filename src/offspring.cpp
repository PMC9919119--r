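#include <Rcpp.h>
using namespace Rcpp;

// Batch construction of offspring load genomes.
//
// For each offspring j, one allele per gene is drawn uniformly from the
// mother's two haplotypes and one from the father's (free recombination:
// genes are unlinked). Segregation bits are taken 16 at a time from the top
// bits of a single unif_rand() draw; all randomness goes through R's RNG so
// set.seed() governs the whole simulation. Mutation to the detrimental state
// (bit 2 of the allele code) is applied per gamete with an exact scheme
// equivalent to independent Bernoulli(mu) per allele: a Binomial(2n, mu)
// count of hits placed at distinct uniform positions (a hit on an
// already-detrimental allele is a no-op, matching idempotent mutation).
//
// Returns the two offspring haplotype matrices plus derived per-offspring
// quantities: heterozygosity, detrimental-allele count and lethality
// (some gene detrimental on both alleles).
// [[Rcpp::export]]
List offspring_load_cpp(IntegerMatrix g1, IntegerMatrix g2,
                        IntegerVector mother, IntegerVector father,
                        double mu) {
  const int M = mother.size();
  const int n = g1.ncol();
  IntegerMatrix o1(M, n), o2(M, n);
  IntegerVector load(M);
  LogicalVector lethal(M);
  NumericVector het(M);

  unsigned int bits = 0;
  int nbits = 0;

  for (int j = 0; j < M; ++j) {
    const int mi = mother[j] - 1;
    const int fi = father[j] - 1;
    for (int k = 0; k < n; ++k) {
      if (nbits < 2) {
        double u = unif_rand();
        bits = (unsigned int)(u * 65536.0);
        if (bits > 65535u) bits = 65535u;
        nbits = 16;
      }
      o1(j, k) = (bits & 1u) ? g1(mi, k) : g2(mi, k);
      bits >>= 1;
      o2(j, k) = (bits & 1u) ? g1(fi, k) : g2(fi, k);
      bits >>= 1;
      nbits -= 2;
    }
    if (mu > 0) {
      int nm = (int) R::rbinom(2.0 * n, mu);
      if (nm > 2 * n) nm = 2 * n;
      int placed[64];
      if (nm > 64) nm = 64;  // unreachable at realistic mu; cap for safety
      for (int m = 0; m < nm; ++m) {
        int pos;
        bool dup;
        do {
          pos = (int)(unif_rand() * (2.0 * n));
          if (pos >= 2 * n) pos = 2 * n - 1;
          dup = false;
          for (int q = 0; q < m; ++q) if (placed[q] == pos) { dup = true; break; }
        } while (dup);
        placed[m] = pos;
        if (pos < n) o1(j, pos) |= 2; else o2(j, pos - n) |= 2;
      }
    }
    int nh = 0, nd = 0;
    bool let = false;
    for (int k = 0; k < n; ++k) {
      const int a = o1(j, k), b = o2(j, k);
      if (a != b) ++nh;
      const bool da = (a & 2) != 0, db = (b & 2) != 0;
      nd += (int)da + (int)db;
      if (da && db) let = true;
    }
    het[j] = (double)nh / n;
    load[j] = nd;
    lethal[j] = let;
  }
  return List::create(_["g1"] = o1, _["g2"] = o2, _["het"] = het,
                      _["load"] = load, _["lethal"] = lethal);
}
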