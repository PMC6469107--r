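#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state recurrence).
// Gap cost convention: a gap of length L costs gapOpen + L * gapExtend.
// Sequences arrive as 0-based indices into the substitution matrix.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_local")]]
List gotoh_local(IntegerVector q, IntegerVector s, NumericMatrix sm,
                 double gapOpen, double gapExtend) {
  int m = q.size(), n = s.size();
  double go = gapOpen + gapExtend, ge = gapExtend;

  // DP matrices, (m+1) x (n+1), row-major vectors
  std::vector<double> M((m + 1) * (n + 1), 0.0);
  std::vector<double> X((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Y((m + 1) * (n + 1), NEG_INF);
  // traceback: tbM 0=start,1=M,2=X,3=Y ; tbX 1=M,2=X ; tbY 1=M,3=Y
  std::vector<signed char> tbM((m + 1) * (n + 1), 0);
  std::vector<signed char> tbX((m + 1) * (n + 1), 1);
  std::vector<signed char> tbY((m + 1) * (n + 1), 1);

  auto idx = [n](int i, int j) { return i * (n + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int k = idx(i, j);
      // gap states
      double xm = M[idx(i - 1, j)] - go, xx = X[idx(i - 1, j)] - ge;
      if (xm >= xx) { X[k] = xm; tbX[k] = 1; } else { X[k] = xx; tbX[k] = 2; }
      double ym = M[idx(i, j - 1)] - go, yy = Y[idx(i, j - 1)] - ge;
      if (ym >= yy) { Y[k] = ym; tbY[k] = 1; } else { Y[k] = yy; tbY[k] = 3; }
      // match state: prefer continuing (M > X > Y) over restarting, for
      // deterministic left-most alignments among ties
      double sub = sm(q[i - 1], s[j - 1]);
      int kd = idx(i - 1, j - 1);
      double cand = M[kd]; signed char tb = 1;
      if (X[kd] > cand) { cand = X[kd]; tb = 2; }
      if (Y[kd] > cand) { cand = Y[kd]; tb = 3; }
      if (cand <= 0.0) { cand = 0.0; tb = 0; }   // restart: local alignment
      M[k] = sub + cand; tbM[k] = tb;
      if (M[k] > best) { best = M[k]; bi = i; bj = j; }
    }
  }

  // empty alignment when nothing scores positive
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["q_idx"] = IntegerVector(0),
                        _["s_idx"] = IntegerVector(0),
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0);
  }

  std::vector<int> qa, sa;
  int i = bi, j = bj;
  int state = 0; // 0 = M
  while (true) {
    int k = idx(i, j);
    if (state == 0) {
      qa.push_back(i); sa.push_back(j);
      signed char tb = tbM[k];
      --i; --j;
      if (tb == 0) break;
      state = (tb == 1) ? 0 : (tb == 2 ? 1 : 2);
    } else if (state == 1) { // X: gap in subject, consume query
      qa.push_back(i); sa.push_back(-1);
      signed char tb = tbX[k];
      --i;
      state = (tb == 1) ? 0 : 1;
    } else {               // Y: gap in query, consume subject
      qa.push_back(-1); sa.push_back(j);
      signed char tb = tbY[k];
      --j;
      state = (tb == 1) ? 0 : 2;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  return List::create(_["score"] = best,
                      _["q_idx"] = wrap(qa), _["s_idx"] = wrap(sa),
                      _["q_start"] = i + 1, _["q_end"] = bi,
                      _["s_start"] = j + 1, _["s_end"] = bj);
}

// Global (Needleman-Wunsch) affine-gap alignment of two profiles.
// A, B: profile matrices (rows = sequences, cols = alignment columns),
// entries are 0-based residue codes or -1 for a gap character.
// Column score = mean over all residue pairs; pairs involving an in-column
// gap contribute 0.
// [[Rcpp::export(name = ".gotoh_global_profile")]]
List gotoh_global_profile(IntegerMatrix A, IntegerMatrix B, NumericMatrix sm,
                          double gapOpen, double gapExtend) {
  int m = A.ncol(), n = B.ncol();
  int ra = A.nrow(), rb = B.nrow();
  double go = gapOpen + gapExtend, ge = gapExtend;

  // precompute column-pair scores
  NumericMatrix cs(m, n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double acc = 0.0;
      for (int a = 0; a < ra; ++a) {
        int ca = A(a, i);
        if (ca < 0) continue;
        for (int b = 0; b < rb; ++b) {
          int cb = B(b, j);
          if (cb < 0) continue;
          acc += sm(ca, cb);
        }
      }
      cs(i, j) = acc / (double)(ra * rb);
    }
  }

  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> X((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Y((m + 1) * (n + 1), NEG_INF);
  std::vector<signed char> tbM((m + 1) * (n + 1), 0);
  std::vector<signed char> tbX((m + 1) * (n + 1), 2);
  std::vector<signed char> tbY((m + 1) * (n + 1), 3);
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) { X[idx(i, 0)] = -(go + (i - 1) * ge); tbX[idx(i, 0)] = (i == 1) ? 1 : 2; }
  for (int j = 1; j <= n; ++j) { Y[idx(0, j)] = -(go + (j - 1) * ge); tbY[idx(0, j)] = (j == 1) ? 1 : 3; }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int k = idx(i, j);
      double xm = M[idx(i - 1, j)] - go, xx = X[idx(i - 1, j)] - ge;
      if (xm >= xx) { X[k] = xm; tbX[k] = 1; } else { X[k] = xx; tbX[k] = 2; }
      double ym = M[idx(i, j - 1)] - go, yy = Y[idx(i, j - 1)] - ge;
      if (ym >= yy) { Y[k] = ym; tbY[k] = 1; } else { Y[k] = yy; tbY[k] = 3; }
      int kd = idx(i - 1, j - 1);
      double cand = M[kd]; signed char tb = 1;
      if (X[kd] > cand) { cand = X[kd]; tb = 2; }
      if (Y[kd] > cand) { cand = Y[kd]; tb = 3; }
      M[k] = cs(i - 1, j - 1) + cand; tbM[k] = tb;
    }
  }

  int ke = idx(m, n);
  double sc = M[ke]; int state = 0;
  if (X[ke] > sc) { sc = X[ke]; state = 1; }
  if (Y[ke] > sc) { sc = Y[ke]; state = 2; }

  std::vector<int> pa, pb;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    int k = idx(i, j);
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      signed char tb = tbM[k];
      --i; --j;
      state = (tb == 1) ? 0 : (tb == 2 ? 1 : 2);
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(-1);
      signed char tb = tbX[k];
      --i;
      state = (tb == 1) ? 0 : 1;
    } else {
      pa.push_back(-1); pb.push_back(j);
      signed char tb = tbY[k];
      --j;
      state = (tb == 1) ? 0 : 2;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = sc,
                      _["a_idx"] = wrap(pa), _["b_idx"] = wrap(pb));
}
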