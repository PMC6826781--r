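// Small vectorized sequence utilities.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t j = 0; j < r.size(); ++j) {
      switch (r[j]) {
        case 'A': case 'a': r[j] = 'T'; break;
        case 'C': case 'c': r[j] = 'G'; break;
        case 'G': case 'g': r[j] = 'C'; break;
        case 'T': case 't': r[j] = 'A'; break;
        default: r[j] = 'N';
      }
    }
    out[i] = r;
  }
  return out;
}
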