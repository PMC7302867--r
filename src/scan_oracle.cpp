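#include <Rcpp.h>
using namespace Rcpp;

// Brute-force reference scanner. For every candidate interval it tests,
// from first principles, (i) that the interval has period p over ACGT
// only, (ii) that no period q < p also holds (smallest-period rule), and
// (iii) two-sided maximality by re-testing the one-base extensions.
// Intentionally naive; serves as the independent oracle for the
// vectorized scanner.

static inline bool is_acgt(unsigned char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// does x[s..e) consist of ACGT only and have period p?
static bool has_period(const unsigned char* x, int n, int s, int e, int p) {
  if (s < 0 || e > n || e - s < p) return false;
  for (int i = s; i < e; ++i)
    if (!is_acgt(x[i])) return false;
  for (int i = s + p; i < e; ++i)
    if (x[i] != x[i - p]) return false;
  return true;
}

// [[Rcpp::export]]
DataFrame scan_bruteforce_cpp(RawVector seq, IntegerVector periods) {
  const unsigned char* x = (const unsigned char*) RAW(seq);
  int n = seq.size();
  std::vector<int> out_start, out_end, out_p;
  for (int pi = 0; pi < periods.size(); ++pi) {
    int p = periods[pi];
    int minlen = (p == 3) ? 9 : 6;
    for (int s = 0; s + minlen <= n; ++s) {
      // walk every end; once period p fails at [s, e) it fails for all
      // longer intervals starting at s
      for (int e = s + minlen; e <= n; ++e) {
        if (!has_period(x, n, s, e, p)) break;
        bool smaller = false;            // smallest-period rule
        for (int q = 1; q < p && !smaller; ++q)
          smaller = has_period(x, n, s, e, q);
        if (smaller) continue;
        bool maximal = !has_period(x, n, s - 1, e, p) &&
                       !has_period(x, n, s, e + 1, p);
        if (!maximal) continue;
        out_start.push_back(s);
        out_end.push_back(e);
        out_p.push_back(p);
      }
    }
  }
  return DataFrame::create(_["start"] = out_start, _["end"] = out_end,
                           _["unit_len"] = out_p);
}
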