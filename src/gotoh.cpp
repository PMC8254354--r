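#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh, three-state DP).
// A gap of length L costs gap_open + L * gap_extend (both <= 0).
// States: 0 = M (a[i] over b[j]), 1 = X (a[i] over '-'), 2 = Y ('-' over b[j]).
// Ties are broken deterministically: M first, then the state that places the
// gap against the longer input (prefer_x = gap characters in b's row first).

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 double match, double mismatch,
                 double gap_open, double gap_extend,
                 bool prefer_x) {
  const int n = a.size(), m = b.size();
  if ((double)(n + 1) * (double)(m + 1) > 4e8)
    stop("sequences too long for dense alignment");
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback: for each state, which predecessor state was used
  std::vector<unsigned char> tM((n + 1) * W), tX((n + 1) * W), tY((n + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + i * gap_extend;
    tX[i * W] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + j * gap_extend;
    tY[j] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M: diagonal from any state; prefer M, then preferred gap state
      {
        double best = M[d]; unsigned char st = 0;
        if (prefer_x) {
          if (X[d] > best) { best = X[d]; st = 1; }
          if (Y[d] > best) { best = Y[d]; st = 2; }
        } else {
          if (Y[d] > best) { best = Y[d]; st = 2; }
          if (X[d] > best) { best = X[d]; st = 1; }
        }
        M[c] = best + s; tM[c] = st;
      }
      // X: consume a[i], gap in b's row
      {
        double open = M[u] + gap_open + gap_extend;
        double ext = X[u] + gap_extend;
        double sw = Y[u] + gap_open + gap_extend;
        double best = open; unsigned char st = 0;
        if (ext > best) { best = ext; st = 1; }
        if (sw > best) { best = sw; st = 2; }
        X[c] = best; tX[c] = st;
      }
      // Y: consume b[j], gap in a's row
      {
        double open = M[l] + gap_open + gap_extend;
        double ext = Y[l] + gap_extend;
        double sw = X[l] + gap_open + gap_extend;
        double best = open; unsigned char st = 0;
        if (ext > best) { best = ext; st = 2; }
        if (sw > best) { best = sw; st = 1; }
        Y[c] = best; tY[c] = st;
      }
    }
  }

  const int end = n * W + m;
  double score = M[end]; unsigned char state = 0;
  if (prefer_x) {
    if (X[end] > score) { score = X[end]; state = 1; }
    if (Y[end] > score) { score = Y[end]; state = 2; }
  } else {
    if (Y[end] > score) { score = Y[end]; state = 2; }
    if (X[end] > score) { score = X[end]; state = 1; }
  }
  if (n == 0 && m == 0) { score = 0.0; state = 0; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0 && i > 0 && j > 0) {
      unsigned char prev = tM[i * W + j];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1 && i > 0) {
      unsigned char prev = tX[i * W + j];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    } else if (state == 2 && j > 0) {
      unsigned char prev = tY[i * W + j];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    } else {
      // boundary: only one direction possible
      state = (i > 0) ? 1 : 2;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}
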