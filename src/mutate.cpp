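#include <Rcpp.h>
using namespace Rcpp;

// Codon-aware point-mutation engine for the forward simulator.
// Candidate substitutions are uniform over positions and alternative bases;
// synonymous candidates are always accepted, nonsynonymous ones with
// probability omega, and candidates creating a stop codon are rejected, so
// open reading frames stay intact. Uses R's RNG (RNGScope via attributes).
//
// seq: bases encoded 0..3 (A,C,G,T); aa_of_codon: length-64 table indexed by
// 16*b1 + 4*b2 + b3, amino-acid code >= 0, stop = -1.

// [[Rcpp::export]]
List mutate_cds_cpp(IntegerVector seq, int n_candidates, double omega,
                    IntegerVector aa_of_codon) {
  IntegerVector s = clone(seq);
  const int L = s.size();
  int n_syn = 0, n_nonsyn = 0;
  for (int k = 0; k < n_candidates; ++k) {
    int pos = (int)(unif_rand() * L);
    if (pos >= L) pos = L - 1;
    int old_base = s[pos];
    int shift = 1 + (int)(unif_rand() * 3);
    if (shift > 3) shift = 3;
    int new_base = (old_base + shift) % 4;
    int c0 = pos - (pos % 3);
    int old_idx = 16 * s[c0] + 4 * s[c0 + 1] + s[c0 + 2];
    int b1 = s[c0], b2 = s[c0 + 1], b3 = s[c0 + 2];
    if (pos == c0) b1 = new_base; else if (pos == c0 + 1) b2 = new_base; else b3 = new_base;
    int new_idx = 16 * b1 + 4 * b2 + b3;
    int old_aa = aa_of_codon[old_idx], new_aa = aa_of_codon[new_idx];
    if (new_aa < 0) continue;               // would create a stop: reject
    if (new_aa == old_aa) {                  // synonymous
      s[pos] = new_base; ++n_syn;
    } else if (unif_rand() < omega) {        // nonsynonymous, purifying filter
      s[pos] = new_base; ++n_nonsyn;
    }
  }
  return List::create(_["seq"] = s, _["n_syn"] = n_syn, _["n_nonsyn"] = n_nonsyn);
}
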