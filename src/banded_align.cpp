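#include <Rcpp.h>
using namespace Rcpp;

// Banded affine-gap local alignment (Smith-Waterman) of an integer-encoded
// query against an integer-encoded subject window. Bases are encoded
// A=0, C=1, G=2, T=3, N=4; N never matches (spacer blocks must not align).
// The band restricts subject position j to i + c0 +/- band for query
// position i (both 1-based). A gap of length L costs gap_open + L*gap_extend
// (penalties are negative). Score-only pass; returns the best cell.

static const int NEG = -1000000000;

struct SwEnd {
  int score;
  int qend;
  int send;
};

static SwEnd sw_band_end(const int *q, int m, const int *s, int n,
                         int c0, int band,
                         int match, int mismatch,
                         int gap_open, int gap_extend) {
  int W = 2 * band + 1;
  std::vector<int> Hprev(W, 0), Hcur(W, 0), Fprev(W, NEG), Fcur(W, NEG);
  SwEnd best; best.score = 0; best.qend = 0; best.send = 0;
  for (int i = 1; i <= m; ++i) {
    int E = NEG;  // gap in query, within row i
    for (int k = 0; k < W; ++k) {
      int j = i + c0 - band + k;
      if (j < 1 || j > n) { Hcur[k] = 0; Fcur[k] = NEG; E = NEG; continue; }
      // E: from (i, j-1) which is column k-1 of this row
      int hl = (k >= 1) ? Hcur[k - 1] : 0;
      int el = E;
      E = std::max(hl + gap_open + gap_extend,
                   (el == NEG) ? NEG : el + gap_extend);
      // F: from (i-1, j) which is column k+1 of previous row
      int hu = (k + 1 < W) ? Hprev[k + 1] : 0;
      int fu = (k + 1 < W) ? Fprev[k + 1] : NEG;
      int F = std::max(hu + gap_open + gap_extend,
                       (fu == NEG) ? NEG : fu + gap_extend);
      Fcur[k] = F;
      // diagonal from (i-1, j-1): same k in previous row
      int qa = q[i - 1], sa = s[j - 1];
      int sub = (qa == sa && qa < 4) ? match : mismatch;
      int hd = Hprev[k] + sub;
      int h = hd;
      if (E > h) h = E;
      if (F > h) h = F;
      if (h < 0) h = 0;
      Hcur[k] = h;
      if (h > best.score) { best.score = h; best.qend = i; best.send = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  return best;
}

//' @noRd
// [[Rcpp::export(name = ".sw_band_align")]]
IntegerVector sw_band_align(IntegerVector q, IntegerVector s,
                            int c0, int band,
                            int match, int mismatch,
                            int gap_open, int gap_extend) {
  int m = q.size(), n = s.size();
  SwEnd fwd = sw_band_end(&q[0], m, &s[0], n, c0, band,
                          match, mismatch, gap_open, gap_extend);
  IntegerVector out(5);
  if (fwd.score <= 0) {
    out[0] = 0; out[1] = NA_INTEGER; out[2] = NA_INTEGER;
    out[3] = NA_INTEGER; out[4] = NA_INTEGER;
    return out;
  }
  // Reverse pass over the prefixes ending at the best cell finds the start
  // of the same optimal local alignment (standard endpoint trick).
  std::vector<int> qr(fwd.qend), sr(fwd.send);
  for (int i = 0; i < fwd.qend; ++i) qr[i] = q[fwd.qend - 1 - i];
  for (int j = 0; j < fwd.send; ++j) sr[j] = s[fwd.send - 1 - j];
  SwEnd rev = sw_band_end(qr.data(), fwd.qend, sr.data(), fwd.send,
                          0, 2 * band,
                          match, mismatch, gap_open, gap_extend);
  out[0] = fwd.score;
  out[1] = fwd.qend - rev.qend + 1;  // q_start
  out[2] = fwd.qend;                 // q_end
  out[3] = fwd.send - rev.send + 1;  // s_start
  out[4] = fwd.send;                 // s_end
  return out;
}
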