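#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// smallest p dividing the motif length such that the motif is a tandem
// power of its first p characters
static int minimal_period(const char* m, int k) {
  for (int p = 1; p < k; ++p) {
    if (k % p != 0) continue;
    bool ok = true;
    for (int i = p; i < k; ++i) {
      if (m[i] != m[i - p]) { ok = false; break; }
    }
    if (ok) return p;
  }
  return k;
}

struct Hit {
  int start;   // 1-based, inclusive
  int end;     // 1-based, inclusive (last base of the last full unit)
  int k;       // motif length
  int n;       // full repeat units
  std::string motif;
};

// Maximal perfect tandem repeats of period 1..6 in one sequence.
// A maximal run of positions j with s[j] == s[j+k] (both in ACGT) defines a
// perfect stretch of length run + k; only full units are reported, and the
// motif must be primitive (minimal period == k) so each tract is reported
// once at its minimal period.
// [[Rcpp::export(name = ".scan_one_sequence")]]
DataFrame scan_one_sequence(std::string seq, IntegerVector min_repeats) {
  const int n = (int) seq.size();
  const char* s = seq.c_str();
  std::vector<Hit> hits;

  for (int k = 1; k <= 6; ++k) {
    const int thr = min_repeats[k - 1];
    int j = 0;
    while (j + k < n) {
      if (is_base(s[j]) && s[j] == s[j + k]) {
        int a = j;
        while (j + k < n && is_base(s[j]) && s[j] == s[j + k]) ++j;
        // run of match positions is [a, j-1]; stretch is s[a .. j-1+k]
        int stretch = (j - a) + k;
        int m = stretch / k;
        if (m >= thr && m >= 2) {
          if (minimal_period(s + a, k) == k) {
            Hit h;
            h.start = a + 1;
            h.end = a + m * k;
            h.k = k;
            h.n = m;
            h.motif = seq.substr(a, k);
            hits.push_back(h);
          }
        }
      } else {
        ++j;
      }
    }
  }

  std::sort(hits.begin(), hits.end(), [](const Hit& x, const Hit& y) {
    if (x.start != y.start) return x.start < y.start;
    if (x.k != y.k) return x.k < y.k;
    return x.end < y.end;
  });

  const int H = (int) hits.size();
  IntegerVector start(H), end(H), mlen(H), nrep(H);
  CharacterVector motif(H);
  for (int i = 0; i < H; ++i) {
    start[i] = hits[i].start;
    end[i] = hits[i].end;
    mlen[i] = hits[i].k;
    nrep[i] = hits[i].n;
    motif[i] = hits[i].motif;
  }
  return DataFrame::create(
    _["start"] = start, _["end"] = end, _["motif"] = motif,
    _["motif_length"] = mlen, _["n_repeats"] = nrep,
    _["stringsAsFactors"] = false);
}
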