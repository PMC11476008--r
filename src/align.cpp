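#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels.
//
// States: M ends in a residue pair, X ends in a gap in the reference
// (consumes query), Y ends in a gap in the query (consumes reference).
// A gap of length k costs gap_open + k * gap_extend.
//
// mode 0: local (Smith-Waterman). mode 1: global with free end gaps
// ("overlap"): every residue of both sequences appears in the output,
// terminal gap runs are unpenalised.
//
// Tie-breaks are deterministic: the earliest (row-major) best-scoring end
// cell is used and traceback prefers substitution columns over gaps.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List align_pair_cpp(IntegerVector q, IntegerVector r, IntegerMatrix sub,
                    int gap_open, int gap_extend, int mode) {
  const int n = q.size(), m = r.size();
  const int open_cost = gap_open + gap_extend;
  IntegerMatrix Mv(n + 1, m + 1), Xv(n + 1, m + 1), Yv(n + 1, m + 1);
  // pointer codes: 0 restart/boundary, 1 from M, 2 from X, 3 from Y
  IntegerMatrix Mp(n + 1, m + 1), Xp(n + 1, m + 1), Yp(n + 1, m + 1);

  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { Mv(i, j) = NEG; Xv(i, j) = NEG; Yv(i, j) = NEG; }

  int best = (mode == 0) ? 0 : NEG, bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int s = sub(q[i - 1] - 1, r[j - 1] - 1);
      // M state
      int base, ptr;
      bool can_start = (mode == 0) || (i == 1 || j == 1);
      base = can_start ? 0 : NEG; ptr = 0;
      if (Mv(i - 1, j - 1) > base) { base = Mv(i - 1, j - 1); ptr = 1; }
      if (Xv(i - 1, j - 1) > base) { base = Xv(i - 1, j - 1); ptr = 2; }
      if (Yv(i - 1, j - 1) > base) { base = Yv(i - 1, j - 1); ptr = 3; }
      if (base > NEG / 2) { Mv(i, j) = base + s; Mp(i, j) = ptr; }
      if (mode == 0 && Mv(i, j) < 0) { Mv(i, j) = NEG; }

      // X state: gap in reference, consumes q[i]
      int xv = NEG, xp = 0;
      if (Mv(i - 1, j) > NEG / 2 && Mv(i - 1, j) - open_cost > xv) { xv = Mv(i - 1, j) - open_cost; xp = 1; }
      if (Xv(i - 1, j) > NEG / 2 && Xv(i - 1, j) - gap_extend > xv) { xv = Xv(i - 1, j) - gap_extend; xp = 2; }
      if (Yv(i - 1, j) > NEG / 2 && Yv(i - 1, j) - open_cost > xv) { xv = Yv(i - 1, j) - open_cost; xp = 3; }
      if (mode == 0 && xv < 0) xv = NEG;
      if (xv > NEG / 2) { Xv(i, j) = xv; Xp(i, j) = xp; }

      // Y state: gap in query, consumes r[j]
      int yv = NEG, yp = 0;
      if (Mv(i, j - 1) > NEG / 2 && Mv(i, j - 1) - open_cost > yv) { yv = Mv(i, j - 1) - open_cost; yp = 1; }
      if (Yv(i, j - 1) > NEG / 2 && Yv(i, j - 1) - gap_extend > yv) { yv = Yv(i, j - 1) - gap_extend; yp = 3; }
      if (Xv(i, j - 1) > NEG / 2 && Xv(i, j - 1) - open_cost > yv) { yv = Xv(i, j - 1) - open_cost; yp = 2; }
      if (mode == 0 && yv < 0) yv = NEG;
      if (yv > NEG / 2) { Yv(i, j) = yv; Yp(i, j) = yp; }

      if (mode == 0) {
        if (Mv(i, j) > best) { best = Mv(i, j); bi = i; bj = j; }
      }
    }
  }

  if (mode == 1) {
    // free trailing gaps: best substitution-ending cell on the last row/col
    for (int j = 1; j <= m; ++j)
      if (Mv(n, j) > best) { best = Mv(n, j); bi = n; bj = j; }
    for (int i = 1; i <= n; ++i)
      if (Mv(i, m) > best) { best = Mv(i, m); bi = i; bj = m; }
    if (n == 0 || m == 0 || best <= NEG / 2) {
      // no substitution column possible; emit pure-gap columns
      std::vector<int> qp, rp;
      for (int i = 1; i <= n; ++i) { qp.push_back(i); rp.push_back(0); }
      for (int j = 1; j <= m; ++j) { qp.push_back(0); rp.push_back(j); }
      IntegerMatrix pairs(qp.size(), 2);
      for (size_t k = 0; k < qp.size(); ++k) { pairs(k, 0) = qp[k]; pairs(k, 1) = rp[k]; }
      return List::create(_["score"] = 0, _["pairs"] = pairs);
    }
  }

  std::vector<int> qp, rp;
  if (!(mode == 0 && best == 0)) {
    int i = bi, j = bj, state = 1;
    while (i > 0 || j > 0) {
      if (state == 1) {
        if (Mv(i, j) <= NEG / 2) break;
        int ptr = Mp(i, j);
        qp.push_back(i); rp.push_back(j);
        --i; --j; state = ptr;
        if (state == 0) break;
      } else if (state == 2) {
        int ptr = Xp(i, j);
        qp.push_back(i); rp.push_back(0);
        --i; state = ptr;
        if (state == 0) break;
      } else if (state == 3) {
        int ptr = Yp(i, j);
        qp.push_back(0); rp.push_back(j);
        --j; state = ptr;
        if (state == 0) break;
      } else break;
    }
    std::reverse(qp.begin(), qp.end());
    std::reverse(rp.begin(), rp.end());
  }

  if (mode == 1 && !qp.empty()) {
    // attach unaligned overhangs as terminal gap columns
    std::vector<int> fq, fr;
    int first_q = 0, first_r = 0;
    for (size_t k = 0; k < qp.size(); ++k) { if (qp[k] > 0) { first_q = qp[k]; break; } }
    for (size_t k = 0; k < rp.size(); ++k) { if (rp[k] > 0) { first_r = rp[k]; break; } }
    for (int i = 1; i < first_q; ++i) { fq.push_back(i); fr.push_back(0); }
    for (int j = 1; j < first_r; ++j) { fq.push_back(0); fr.push_back(j); }
    fq.insert(fq.end(), qp.begin(), qp.end());
    fr.insert(fr.end(), rp.begin(), rp.end());
    int last_q = 0, last_r = 0;
    for (int k = (int)qp.size() - 1; k >= 0; --k) { if (qp[k] > 0) { last_q = qp[k]; break; } }
    for (int k = (int)rp.size() - 1; k >= 0; --k) { if (rp[k] > 0) { last_r = rp[k]; break; } }
    for (int i = last_q + 1; i <= n; ++i) { fq.push_back(i); fr.push_back(0); }
    for (int j = last_r + 1; j <= m; ++j) { fq.push_back(0); fr.push_back(j); }
    qp = fq; rp = fr;
  }

  IntegerMatrix pairs(qp.size(), 2);
  for (size_t k = 0; k < qp.size(); ++k) { pairs(k, 0) = qp[k]; pairs(k, 1) = rp[k]; }
  return List::create(_["score"] = (mode == 0 && best < 0) ? 0 : best,
                      _["pairs"] = pairs);
}
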