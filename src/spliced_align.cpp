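// Banded spliced alignment of a long read against a metagene (intron-free
// exon concatenation). Semi-global: the read is aligned end to end, target
// overhangs at either end are free. Target gaps use a two-piece cost so that
// short gaps (sequencing deletions) and long gaps (whole skipped exons) are
// both modelled: the DP keeps separate affine states for each piece and
// reports them as CIGAR 'D' and 'N' respectively.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

static const double NEG_INF = -1e18;

// traceback byte layout:
//   bits 0-1 : source of H  (0 diag, 1 F, 2 E1, 3 E2)
//   bit  2   : F reached by extension
//   bit  3   : E1 reached by extension
//   bit  4   : E2 reached by extension
// [[Rcpp::export(name = ".spliced_align_cpp")]]
List spliced_align_cpp(std::string read, std::string target,
                       double match, double mismatch,
                       double gap_open_read, double gap_ext_read,
                       double gap_open_del, double gap_ext_del,
                       double gap_open_skip, double gap_ext_skip,
                       int band_slack) {
  const int n = (int) read.size();
  const int m = (int) target.size();
  if (n == 0 || m == 0)
    stop("empty read or target");

  const int diff = m - n;
  const int lo = (diff < 0 ? diff : 0) - band_slack;       // min of j - i
  const int hi = (diff > 0 ? diff : 0) + band_slack;       // max of j - i
  const int W  = hi - lo + 1;

  std::vector<double> Hprev(W, NEG_INF), Hcur(W, NEG_INF);
  std::vector<double> Fprev(W, NEG_INF), Fcur(W, NEG_INF);
  std::vector<uint8_t> tb((size_t) (n + 1) * W, 0);

  // row 0: free leading target gap
  for (int d = 0; d < W; ++d) {
    int j = 0 + lo + d;
    if (j >= 0 && j <= m) Hprev[d] = 0.0;
  }

  for (int i = 1; i <= n; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), NEG_INF);
    std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
    double e1 = NEG_INF, e2 = NEG_INF;
    double hleft = NEG_INF; // H(i, j-1), from previous d in this row
    const char rc = read[i - 1];
    uint8_t *tbrow = &tb[(size_t) i * W];
    for (int d = 0; d < W; ++d) {
      const int j = i + lo + d;
      if (j < 0 || j > m) { hleft = NEG_INF; continue; }

      // F: gap in target (read insertion), consumes read base i
      double hup = (d + 1 < W) ? Hprev[d + 1] : NEG_INF;
      double fup = (d + 1 < W) ? Fprev[d + 1] : NEG_INF;
      double f_open = (hup > NEG_INF / 2) ? hup - gap_open_read : NEG_INF;
      double f_ext  = (fup > NEG_INF / 2) ? fup - gap_ext_read  : NEG_INF;
      uint8_t fbit = 0;
      double f;
      if (f_ext >= f_open) { f = f_ext; fbit = 4; } else f = f_open;
      Fcur[d] = f;

      // E1/E2: gap in read (target deletion / skip), consume target base j
      uint8_t e1bit = 0, e2bit = 0;
      if (j >= 1) {
        double e1_open = (hleft > NEG_INF / 2) ? hleft - gap_open_del : NEG_INF;
        double e1_ext  = (e1 > NEG_INF / 2)    ? e1 - gap_ext_del     : NEG_INF;
        if (e1_ext >= e1_open) { e1 = e1_ext; e1bit = 8; } else e1 = e1_open;
        double e2_open = (hleft > NEG_INF / 2) ? hleft - gap_open_skip : NEG_INF;
        double e2_ext  = (e2 > NEG_INF / 2)    ? e2 - gap_ext_skip     : NEG_INF;
        if (e2_ext >= e2_open) { e2 = e2_ext; e2bit = 16; } else e2 = e2_open;
      } else {
        e1 = e2 = NEG_INF;
      }

      double h; uint8_t src;
      if (j == 0) {
        h = f; src = 1;  // only a read gap can sit before any target base
      } else {
        double hdiag = Hprev[d]; // (i-1, j-1) has the same d
        double sub = (rc == target[j - 1] && rc != 'N') ? match : mismatch;
        h = (hdiag > NEG_INF / 2) ? hdiag + sub : NEG_INF;
        src = 0;
        if (f  > h) { h = f;  src = 1; }
        if (e1 > h) { h = e1; src = 2; }
        if (e2 > h) { h = e2; src = 3; }
      }
      Hcur[d] = h;
      tbrow[d] = (uint8_t) (src | fbit | e1bit | e2bit);
      hleft = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  // free trailing target gap: best score anywhere on the last row
  double best = NEG_INF; int bestd = -1;
  for (int d = 0; d < W; ++d) {
    int j = n + lo + d;
    if (j < 0 || j > m) continue;
    if (Hprev[d] > best) { best = Hprev[d]; bestd = d; }
  }
  if (bestd < 0 || best <= NEG_INF / 2)
    stop("alignment band too narrow for this read/target pair; increase band_slack");

  // traceback
  std::string ops;  // reversed op-per-base string
  ops.reserve((size_t) n + 64);
  int i = n, j = n + lo + bestd;
  int state = 0; // 0 = H, 1 = F, 2 = E1, 3 = E2
  long n_match = 0, n_mismatch = 0, n_ins = 0, n_del = 0, n_skip = 0;
  while (i > 0) {
    const int d = j - i - lo;
    const uint8_t b = tb[(size_t) i * W + d];
    if (state == 0) {
      const uint8_t src = b & 3;
      if (src == 0) {
        ops.push_back('M');
        if (read[i - 1] == target[j - 1] && read[i - 1] != 'N') ++n_match;
        else ++n_mismatch;
        --i; --j;
      } else state = src;
    } else if (state == 1) {       // F: read insertion
      ops.push_back('I'); ++n_ins;
      if (!(b & 4)) state = 0;
      --i;
    } else if (state == 2) {       // E1: short target deletion
      ops.push_back('D'); ++n_del;
      if (!(b & 8)) state = 0;
      --j;
    } else {                       // E2: long target gap (skip)
      ops.push_back('N'); ++n_skip;
      if (!(b & 16)) state = 0;
      --j;
    }
  }
  // any residual E state at i == 0 would be a leading target gap, which is
  // free and therefore never chosen; j is now the 0-based target start.
  const int pos = j;

  // run-length encode the reversed op string
  std::string cigar;
  cigar.reserve(64);
  int k = (int) ops.size() - 1;
  while (k >= 0) {
    char op = ops[k];
    int run = 0;
    while (k >= 0 && ops[k] == op) { ++run; --k; }
    cigar += std::to_string(run);
    cigar.push_back(op);
  }

  return List::create(
    _["pos"] = pos,
    _["cigar"] = cigar,
    _["score"] = best,
    _["n_match"] = (double) n_match,
    _["n_mismatch"] = (double) n_mismatch,
    _["n_ins"] = (double) n_ins,
    _["n_del"] = (double) n_del,
    _["n_skip"] = (double) n_skip);
}
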