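#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Canonical k-mer counting over 2-bit packed sequence (k <= 32).
// Returns the multiplicity histogram directly; k-mer identities are
// never materialised in R.  K-mers overlapping a non-ACGT base are
// skipped and counted.

// [[Rcpp::export]]
List kmer_count_cpp(CharacterVector reads, int k, int max_mult) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  if (max_mult < 1) stop("max_mult must be >= 1");
  std::unordered_map<uint64_t, uint32_t> tab;
  double counted = 0.0, skipped = 0.0;
  const int shift = 2 * (k - 1);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    SEXP sr = STRING_ELT(reads, r);
    if (sr == NA_STRING) continue;
    const char *s = CHAR(sr);
    const int len = LENGTH(sr);
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    long read_counted = 0;
    for (int i = 0; i < len; ++i) {
      int code;
      switch (s[i]) {
        case 'A': case 'a': code = 0; break;
        case 'C': case 'c': code = 1; break;
        case 'G': case 'g': code = 2; break;
        case 'T': case 't': code = 3; break;
        default: code = -1;
      }
      if (code < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)code) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - code) << shift);
      if (++valid >= k) {
        const uint64_t canon = fwd < rev ? fwd : rev;
        ++tab[canon];
        ++read_counted;
      }
    }
    const long windows = len >= k ? len - k + 1 : 0;
    counted += read_counted;
    skipped += windows - read_counted;
  }
  IntegerVector hist(max_mult);
  for (const auto &kv : tab) {
    int m = kv.second > (uint32_t)max_mult ? max_mult : (int)kv.second;
    ++hist[m - 1];
  }
  return List::create(_["hist"] = hist,
                      _["total_kmers"] = counted,
                      _["skipped"] = skipped,
                      _["distinct"] = (double)tab.size());
}
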