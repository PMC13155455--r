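#include <Rcpp.h>
using namespace Rcpp;

// Complement pairing over {A,C,G,T,N}: N never pairs.
static inline bool pairs(char a, char b) {
  switch (a) {
  case 'A': return b == 'T';
  case 'C': return b == 'G';
  case 'G': return b == 'C';
  case 'T': return b == 'A';
  default:  return false;
  }
}

// Exhaustive maximal perfect inverted-repeat detection.
//
// For every spacer length d in [0, max_spacer] and every innermost arm pair
// (e, e + d + 1), arms are extended outward while bases complement. A hit is
// kept only if it is maximal: not outward-extendable (by construction of the
// run) and, for d >= 2, not inward-extendable (the spacer's flanking pair
// must not complement, otherwise the same center carries a longer-armed IR
// at spacer d - 2 which is enumerated separately).
//
// Coordinates returned are 1-based inclusive full spans.
// [[Rcpp::export]]
DataFrame cpp_detect_ir(std::string seq, int min_arm, int max_spacer) {
  const int n = (int) seq.size();
  std::vector<int> starts, ends, arms, spacers;

  for (int d = 0; d <= max_spacer; ++d) {
    for (int e = 0; e + d + 1 < n; ++e) {
      if (!pairs(seq[e], seq[e + d + 1])) continue;
      // inward maximality: spacer ends must not complement
      if (d >= 2 && pairs(seq[e + 1], seq[e + d])) continue;
      int a = 1;
      while (e - a >= 0 && e + d + 1 + a < n &&
             pairs(seq[e - a], seq[e + d + 1 + a])) ++a;
      if (a < min_arm) continue;
      starts.push_back(e - a + 2);              // 1-based
      ends.push_back(e + d + 1 + a);            // 1-based inclusive
      arms.push_back(a);
      spacers.push_back(d);
    }
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["arm_length"] = arms,
                           _["spacer_length"] = spacers);
}
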