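#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch-Gotoh) alignment with affine gaps.
// A gap run of length g scores gap_open + g * gap_extend (both <= 0),
// i.e. the first gap base pays gap_open + gap_extend.
// Deterministic tie-break in the traceback: substitution state first,
// then gap-in-b (consuming a), then gap-in-a.

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix submat,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  // map characters to substitution-matrix rows via dimnames
  List dn = submat.attr("dimnames");
  CharacterVector rn = dn[0];
  std::vector<int> lut(256, -1);
  for (int i = 0; i < rn.size(); ++i) {
    std::string s = as<std::string>(rn[i]);
    lut[(unsigned char)s[0]] = i;
  }
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = lut[(unsigned char)a[i]];
    if (ai[i] < 0) stop("character not in scoring alphabet: %s",
                        std::string(1, a[i]));
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = lut[(unsigned char)b[j]];
    if (bi[j] < 0) stop("character not in scoring alphabet: %s",
                        std::string(1, b[j]));
  }

  const double NEG = -std::numeric_limits<double>::infinity();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // traceback: which predecessor state (0=M,1=X,2=Y, -1 none)
  std::vector<signed char> tM((n + 1) * W, -1), tX((n + 1) * W, -1),
      tY((n + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + i * gap_extend;
    tX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + j * gap_extend;
    tY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int k = i * W + j, kd = (i - 1) * W + (j - 1),
                ku = (i - 1) * W + j, kl = i * W + (j - 1);
      const double s = submat(ai[i - 1], bi[j - 1]);
      // M: tie-break M > X > Y
      double best = M[kd];
      signed char who = 0;
      if (X[kd] > best) { best = X[kd]; who = 1; }
      if (Y[kd] > best) { best = Y[kd]; who = 2; }
      if (best > NEG) { M[k] = best + s; tM[k] = who; }
      // X: consume a[i-1] against a gap
      double xo = (M[ku] > Y[ku] ? M[ku] : Y[ku]) + gap_open + gap_extend;
      signed char xw = (M[ku] >= Y[ku]) ? 0 : 2;
      double xe = X[ku] + gap_extend;
      if (xo >= xe) { X[k] = xo; tX[k] = xw; }
      else { X[k] = xe; tX[k] = 1; }
      // Y: consume b[j-1] against a gap
      double yo = (M[kl] > X[kl] ? M[kl] : X[kl]) + gap_open + gap_extend;
      signed char yw = (M[kl] >= X[kl]) ? 0 : 1;
      double ye = Y[kl] + gap_extend;
      if (yo >= ye) { Y[k] = yo; tY[k] = yw; }
      else { Y[k] = ye; tY[k] = 2; }
    }
  }

  const int kend = n * W + m;
  double score = M[kend];
  int state = 0;
  if (X[kend] > score) { score = X[kend]; state = 1; }
  if (Y[kend] > score) { score = Y[kend]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int k = i * W + j;
    if (state == 0) {
      signed char prev = tM[k];
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      signed char prev = tX[k];
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
      state = prev;
    } else {
      signed char prev = tY[k];
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
      state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = score);
}
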