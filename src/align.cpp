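#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps and a fixed,
// deterministic tie-break so gap placement is reproducible run to run.
//
// States: M = aligned pair (match/mismatch), X = gap in the off-target
// (target base opposite '-', an RNA bulge), Y = gap in the target (extra
// off-target base, a DNA bulge). Gap of length k scores open + (k-1)*extend.
//
// Tie-break, applied both when choosing the final state and at every
// traceback step: prefer M over X over Y. This pushes ambiguous gaps as far
// 3' (PAM-proximal) as the score allows, which is the fixed convention the
// encoders downstream rely on.
//
// lock_pam: gaps are forbidden within the last 3 target positions (the NGG
// PAM frame): state X is disallowed while consuming a PAM base, and state Y
// is disallowed once the PAM frame has been entered (including trailing
// insertions), so the off-target PAM always aligns gap-free to the target
// PAM.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List align_pair_cpp(std::string target, std::string offtarget,
                    double match, double mismatch,
                    double gap_open, double gap_extend,
                    bool lock_pam) {
  const int n = target.size();
  const int m = offtarget.size();
  const int W = m + 1;

  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // pointers: previous state 0=M,1=X,2=Y; -1 unset
  std::vector<signed char> pM((n + 1) * W, -1), pX((n + 1) * W, -1),
      pY((n + 1) * W, -1);

  // PAM frame: target positions n-2..n (1-based) when locking
  const int pam_start = n - 2; // 1-based first PAM position
  auto x_allowed = [&](int i) { // consuming target base i (1-based)
    return !lock_pam || i < pam_start;
  };
  auto y_allowed = [&](int i) { // gap sits after target base i
    return !lock_pam || i < pam_start;
  };

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    if (!x_allowed(i)) break;
    X[i * W] = gap_open + (i - 1) * gap_extend;
    pX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    if (!y_allowed(0)) break;
    Y[j] = gap_open + (j - 1) * gap_extend;
    pY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      // M state
      {
        const double s = (target[i - 1] == offtarget[j - 1]) ? match : mismatch;
        const int d = (i - 1) * W + (j - 1);
        double best = M[d];
        signed char ptr = 0;
        if (X[d] > best) { best = X[d]; ptr = 1; }
        if (Y[d] > best) { best = Y[d]; ptr = 2; }
        if (best > NEG_INF / 2) { M[idx] = best + s; pM[idx] = ptr; }
      }
      // X state: consume target i, '-' in offtarget
      if (x_allowed(i)) {
        const int u = (i - 1) * W + j;
        double best = M[u] + gap_open;
        signed char ptr = 0;
        if (X[u] + gap_extend > best) { best = X[u] + gap_extend; ptr = 1; }
        if (Y[u] + gap_open > best) { best = Y[u] + gap_open; ptr = 2; }
        if (best > NEG_INF / 2) { X[idx] = best; pX[idx] = ptr; }
      }
      // Y state: consume offtarget j, '-' in target (gap after target base i)
      if (y_allowed(i)) {
        const int l = i * W + (j - 1);
        double best = M[l] + gap_open;
        signed char ptr = 0;
        if (X[l] + gap_open > best) { best = X[l] + gap_open; ptr = 1; }
        if (Y[l] + gap_extend > best) { best = Y[l] + gap_extend; ptr = 2; }
        if (best > NEG_INF / 2) { Y[idx] = best; pY[idx] = ptr; }
      }
    }
  }

  const int end = n * W + m;
  double score = M[end];
  int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }
  if (score < NEG_INF / 2)
    stop("no feasible alignment under the given constraints");

  std::string ta, oa;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      const signed char ptr = pM[i * W + j];
      ta.push_back(target[i - 1]);
      oa.push_back(offtarget[j - 1]);
      --i; --j;
      state = ptr;
    } else if (state == 1) {
      const signed char ptr = pX[i * W + j];
      ta.push_back(target[i - 1]);
      oa.push_back('-');
      --i;
      state = ptr;
    } else {
      const signed char ptr = pY[i * W + j];
      ta.push_back('-');
      oa.push_back(offtarget[j - 1]);
      --j;
      state = ptr;
    }
  }
  std::reverse(ta.begin(), ta.end());
  std::reverse(oa.begin(), oa.end());

  return List::create(_["target_aln"] = ta, _["offtarget_aln"] = oa,
                      _["score"] = score);
}
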