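#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Ungapped scan of a read against every offset of every reference on the
// given strand. Characters other than an exact A/C/G/T match count as
// mismatches (so N is always a mismatch). Returns, for each reference,
// the minimum mismatch count over offsets (or NA if it exceeds
// max_mismatch at every offset) plus the best offset (0-based).
// [[Rcpp::export]]
List cpp_scan_read(std::string read, CharacterVector refs, int max_mismatch) {
  int n = refs.size();
  int L = read.size();
  IntegerVector best(n, NA_INTEGER), off(n, NA_INTEGER);
  for (int j = 0; j < n; ++j) {
    std::string ref = as<std::string>(refs[j]);
    int RL = ref.size();
    if (L > RL) continue;
    int bj = max_mismatch + 1, bo = -1;
    for (int o = 0; o + L <= RL; ++o) {
      int mm = 0;
      for (int k = 0; k < L; ++k) {
        if (read[k] != ref[o + k]) {
          if (++mm >= bj) break;  // cannot beat current best
        }
      }
      if (mm < bj) { bj = mm; bo = o; if (bj == 0) break; }
    }
    if (bj <= max_mismatch) { best[j] = bj; off[j] = bo; }
  }
  return List::create(_["mismatches"] = best, _["offset"] = off);
}
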