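#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// Semi-global affine Needleman-Wunsch of a read against one unaligned
// seed row, returning the read written in seed coordinates: '.' outside
// the aligned span, '-' where the read has a deletion, and read bases
// elsewhere. Read insertions relative to the seed are dropped (NAST
// behaviour) so all reads share the seed's column system. The read is
// consumed in full; leading/trailing seed positions are free.
//
// Scores are kept in int16 (scaled x2: match +2, mismatch -2, open -8,
// extend -2) to halve memory traffic over the DP tables; with path
// penalties bounded by ~8 per step and sequences of a few hundred
// bases, scores stay far from the int16 range.
// [[Rcpp::export]]
String cpp_nast_align(std::string read, std::string ref,
                      double match = 1.0, double mismatch = -1.0,
                      double gap_open = 4.0, double gap_extend = 1.0) {
  const int m = read.size(), L = ref.size();
  if (m == 0 || L == 0) stop("empty sequence");
  if (m > 5000 || L > 5000) stop("sequence too long for int16 scores");
  typedef int16_t score_t;
  const score_t NEG = -20000;
  const score_t sm = (score_t)std::lround(2 * match);
  const score_t sx = (score_t)std::lround(2 * mismatch);
  const score_t go = (score_t)std::lround(2 * gap_open);
  const score_t ge = (score_t)std::lround(2 * gap_extend);
  // D: read i on ref j; P: ref j gapped against read ('-');
  // Q: read i inserted (dropped)
  std::vector<score_t> D((m + 1) * (L + 1), NEG),
      P((m + 1) * (L + 1), NEG), Q((m + 1) * (L + 1), NEG);
  std::vector<unsigned char> bD((m + 1) * (L + 1), 0),
      bP((m + 1) * (L + 1), 0), bQ((m + 1) * (L + 1), 0);
  auto at = [L](int i, int j) { return i * (L + 1) + j; };

  for (int j = 0; j <= L; ++j) D[at(0, j)] = 0;    // free leading seed
  for (int i = 1; i <= m; ++i) {
    const char rc = read[i - 1];
    const score_t *Dp = &D[at(i - 1, 0)], *Pp = &P[at(i - 1, 0)],
                  *Qp = &Q[at(i - 1, 0)];
    score_t *Di = &D[at(i, 0)], *Pi = &P[at(i, 0)], *Qi = &Q[at(i, 0)];
    unsigned char *bDi = &bD[at(i, 0)], *bPi = &bP[at(i, 0)],
                  *bQi = &bQ[at(i, 0)];
    for (int j = 1; j <= L; ++j) {
      const score_t s = (rc == ref[j - 1]) ? sm : sx;
      // diagonal
      score_t best = Dp[j - 1]; unsigned char bt = 1;
      if (Pp[j - 1] > best) { best = Pp[j - 1]; bt = 2; }
      if (Qp[j - 1] > best) { best = Qp[j - 1]; bt = 3; }
      Di[j] = best + s; bDi[j] = bt;
      // deletion in read (consume ref)
      const score_t po = Di[j - 1] - go;
      const score_t pe = Pi[j - 1] - ge;
      if (po >= pe) { Pi[j] = po; bPi[j] = 1; }
      else { Pi[j] = pe; bPi[j] = 2; }
      // insertion in read (consume read)
      const score_t qo = Dp[j] - go;
      const score_t qe = Qp[j] - ge;
      if (qo >= qe) { Qi[j] = qo; bQi[j] = 1; }
      else { Qi[j] = qe; bQi[j] = 3; }
    }
  }
  // free trailing seed positions: best end anywhere in row m
  int ej = 1; unsigned char es = 1; score_t best = NEG;
  for (int j = 1; j <= L; ++j) {
    if (D[at(m, j)] > best) { best = D[at(m, j)]; ej = j; es = 1; }
    if (Q[at(m, j)] > best) { best = Q[at(m, j)]; ej = j; es = 3; }
  }
  std::string row(L, '.');
  int i = m, j = ej; unsigned char state = es;
  while (i > 0 && j >= 0) {
    if (state == 1) {          // D: read i-1 at ref j-1
      row[j - 1] = read[i - 1];
      state = bD[at(i, j)]; --i; --j;
      if (i == 0) break;
    } else if (state == 2) {   // P: ref j-1 gapped
      row[j - 1] = '-';
      state = bP[at(i, j)]; --j;
    } else {                   // Q: read i-1 dropped
      state = bQ[at(i, j)]; --i;
      if (i == 0) break;
    }
  }
  return String(row);
}
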