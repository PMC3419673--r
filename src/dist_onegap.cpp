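#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

#ifdef _MSC_VER
#include <intrin.h>
static inline int popcount64(uint64_t x) { return (int)__popcnt64(x); }
#else
static inline int popcount64(uint64_t x) {
  return __builtin_popcountll(x);
}
#endif

// Pairwise distance over equal-width filtered alignment rows.
// Rules: columns gapped in both rows are skipped; a maximal run of gap
// columns in exactly one row counts as a single mismatch event and as a
// single compared column; terminal-gap '.' columns are treated like
// gaps. distance = (substitutions + gap runs) / compared columns.
//
// Rows are packed into 2-bit base planes plus a gap mask so that
// substitution and comparable-column counts reduce to XOR/AND +
// popcount; gap-run events are counted by walking only the (sparse)
// set of columns where at least one row is gapped, preserving the
// run-state semantics across mutual-gap columns. Non-ACGT, non-gap
// characters are not expected after quality control and are encoded
// as 'A'.
// [[Rcpp::export]]
NumericMatrix cpp_dist_onegap(CharacterVector rows) {
  const int n = rows.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(rows[i]);
  const size_t L = n ? s[0].size() : 0;
  for (int i = 0; i < n; ++i)
    if (s[i].size() != L) stop("rows must have equal width");
  const size_t W = (L + 63) / 64;

  std::vector<uint64_t> B0(n * W, 0), B1(n * W, 0), G(n * W, 0);
  for (int i = 0; i < n; ++i) {
    for (size_t c = 0; c < L; ++c) {
      const char ch = s[i][c];
      const size_t w = c >> 6;
      const uint64_t bit = 1ULL << (c & 63);
      uint8_t code = 0;
      switch (ch) {
        case 'A': code = 0; break;
        case 'C': code = 1; break;
        case 'G': code = 2; break;
        case 'T': code = 3; break;
        case '-': case '.': G[i * W + w] |= bit; continue;
        default: code = 0;
      }
      if (code & 1) B0[i * W + w] |= bit;
      if (code & 2) B1[i * W + w] |= bit;
    }
  }

  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    const uint64_t *b0i = &B0[i * W], *b1i = &B1[i * W], *gi = &G[i * W];
    for (int j = i + 1; j < n; ++j) {
      const uint64_t *b0j = &B0[j * W], *b1j = &B1[j * W],
                     *gj = &G[j * W];
      long compared = 0, subs = 0, events = 0;
      bool any_gap = false;
      for (size_t w = 0; w < W; ++w) {
        const uint64_t both = ~(gi[w] | gj[w]) &
          ((w == W - 1 && (L & 63))
             ? ((1ULL << (L & 63)) - 1) : ~0ULL);
        compared += popcount64(both);
        subs += popcount64(((b0i[w] ^ b0j[w]) | (b1i[w] ^ b1j[w])) &
                           both);
        if (gi[w] | gj[w]) any_gap = true;
      }
      if (any_gap) {
        // walk the union of gapped columns, counting run starts; a
        // column gapped in both rows neither starts nor breaks a run,
        // while any interposed non-gap column resets the state
        int run = 0;
        long prev_c = -2;
        for (size_t w = 0; w < W; ++w) {
          uint64_t u = gi[w] | gj[w];
          while (u) {
            const int b = __builtin_ctzll(u);
            u &= u - 1;
            const long c = (long)(w << 6) + b;
            if (c >= (long)L) break;
            if (c > prev_c + 1) run = 0;
            const bool ga = (gi[w] >> b) & 1ULL;
            const bool gb = (gj[w] >> b) & 1ULL;
            if (!(ga && gb)) {
              const int type = ga ? 1 : 2;
              if (run != type) { ++events; run = type; }
            }
            prev_c = c;
          }
        }
      }
      const long denom = compared + events;
      if (denom == 0) {
        out(i, j) = out(j, i) = NA_REAL;
      } else {
        out(i, j) = out(j, i) =
          double(subs + events) / double(denom);
      }
    }
  }
  return out;
}
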