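#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Maximal Hamming-bounded matching windows between two strings, scanned
// diagonal by diagonal. A window on diagonal d (= j - i, 0-based) is
// maximal when it cannot be extended on either side without exceeding
// max_mm mismatches or leaving the sequences. 'N' (or any non-ACGT char)
// never matches, not even itself. Returns 1-based (i, j, len, mm).
//
// The full diagonal sweep is exact: unlike pigeonhole seeding, it cannot
// miss windows on AT-rich sequences where short seeds saturate.
// [[Rcpp::export(name = ".diagonal_maximal_pairs")]]
IntegerMatrix diagonal_maximal_pairs(std::string s, std::string t,
                                     int min_len, int max_mm,
                                     int dmin, int dmax) {
  const int n = (int) s.size();
  const int m = (int) t.size();
  std::vector<int> oi, oj, olen, omm;
  std::vector<int> mm_pos;  // mismatch offsets within the current overlap

  auto is_match = [](char a, char b) {
    if (a != b) return false;
    return a == 'A' || a == 'C' || a == 'G' || a == 'T';
  };

  for (int d = dmin; d <= dmax; ++d) {
    // overlap in 0-based i coordinates: i in [i0, i1], j = i + d
    int i0 = std::max(0, -d);
    int i1 = std::min(n - 1, m - 1 - d);
    int L = i1 - i0 + 1;
    if (L < min_len) continue;
    mm_pos.clear();
    for (int x = 0; x < L; ++x) {
      if (!is_match(s[i0 + x], t[i0 + x + d])) mm_pos.push_back(x);
    }
    int tmm = (int) mm_pos.size();
    auto emit = [&](int w0, int w1, int mm) {
      int len = w1 - w0 + 1;
      if (len < min_len) return;
      oi.push_back(i0 + w0 + 1);
      oj.push_back(i0 + w0 + d + 1);
      olen.push_back(len);
      omm.push_back(mm);
    };
    if (tmm <= max_mm) {
      emit(0, L - 1, tmm);
    } else {
      for (int idx = 0; idx + max_mm <= tmm; ++idx) {
        int w0 = (idx == 0) ? 0 : mm_pos[idx - 1] + 1;
        int w1 = (idx + max_mm < tmm) ? mm_pos[idx + max_mm] - 1 : L - 1;
        emit(w0, w1, max_mm);
      }
    }
  }
  IntegerMatrix out((int) oi.size(), 4);
  for (int r = 0; r < (int) oi.size(); ++r) {
    out(r, 0) = oi[r];
    out(r, 1) = oj[r];
    out(r, 2) = olen[r];
    out(r, 3) = omm[r];
  }
  colnames(out) = CharacterVector::create("i", "j", "len", "mm");
  return out;
}
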