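#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). A gap of length k costs open + k * ext,
// i.e. the first gapped position already pays open + ext.

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// Core score-only DP over an arbitrary match-score accessor.
// S(i, j) = score of aligning query residue i to target position j.
template <typename Accessor>
static double sw_score_core(int qlen, int tlen, Accessor S,
                            double go, double ge) {
  if (qlen == 0 || tlen == 0) return 0.0;
  std::vector<double> H(tlen + 1, 0.0), E(tlen + 1, R_NegInf);
  double best = 0.0;
  for (int i = 1; i <= qlen; ++i) {
    double diag = 0.0;        // H[i-1][j-1]
    double F = R_NegInf;      // gap in target (vertical)
    H[0] = 0.0;
    for (int j = 1; j <= tlen; ++j) {
      E[j] = std::max(H[j - 1] - go - ge, E[j] - ge);
      F = std::max(H[j] - go - ge, F - ge);
      double h = max3(diag + S(i - 1, j - 1), E[j], F);
      if (h < 0.0) h = 0.0;
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_batch")]]
NumericVector sw_score_batch(List queries, List targets, NumericMatrix M,
                             double gapOpen, double gapExt, bool cross) {
  // cross = TRUE: all query x target combinations (row-major, query outer);
  // cross = FALSE: paired (same length lists).
  int nq = queries.size(), nt = targets.size();
  int nA = M.nrow();
  const double *Mp = M.begin();
  int nout = cross ? nq * nt : nq;
  NumericVector out(nout);
  for (int a = 0; a < nq; ++a) {
    IntegerVector q = queries[a];
    const int *qp = q.begin();
    int bmax = cross ? nt : 1;
    for (int b = 0; b < bmax; ++b) {
      IntegerVector t = cross ? targets[b] : targets[a];
      const int *tp = t.begin();
      double sc = sw_score_core(q.size(), t.size(),
        [&](int i, int j) { return Mp[qp[i] + tp[j] * nA]; }, gapOpen, gapExt);
      out[cross ? a * nt + b : a] = sc;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".profile_score_batch")]]
NumericVector profile_score_batch(List queries, NumericMatrix prof,
                                  double gapOpen, double gapExt) {
  // prof: nAlpha x nColumns position-specific scores. Transposed once so
  // each residue's scores across target columns are contiguous.
  int nq = queries.size(), tlen = prof.ncol(), nA = prof.nrow();
  std::vector<double> T((size_t)tlen * nA);
  for (int a = 0; a < nA; ++a)
    for (int j = 0; j < tlen; ++j)
      T[(size_t)a * tlen + j] = prof(a, j);
  NumericVector out(nq);
  for (int a = 0; a < nq; ++a) {
    IntegerVector q = queries[a];
    int qlen = q.size();
    std::vector<const double *> rows(qlen);
    for (int i = 0; i < qlen; ++i) rows[i] = &T[(size_t)q[i] * tlen];
    out[a] = sw_score_core(qlen, tlen,
      [&](int i, int j) { return rows[i][j]; }, gapOpen, gapExt);
  }
  return out;
}

// Full DP with traceback on an explicit score matrix S (qlen x tlen).
// Returns best score, spans, and the matched (query, target) index pairs
// (1-based) along the optimal local alignment.
// [[Rcpp::export(name = ".sw_align_scores")]]
List sw_align_scores(NumericMatrix S, double gapOpen, double gapExt) {
  int qlen = S.nrow(), tlen = S.ncol();
  if (qlen == 0 || tlen == 0)
    return List::create(_["score"] = 0.0, _["pairs"] = IntegerMatrix(0, 2));
  size_t W = tlen + 1, NC = (qlen + 1) * W;
  std::vector<double> H(NC, 0.0), E(NC, R_NegInf), F(NC, R_NegInf);
  // tbH: 0 stop, 1 diag, 2 from E, 3 from F; tbE/tbF: 1 opened from H, 0 extended
  std::vector<unsigned char> tbH(NC, 0), tbE(NC, 0), tbF(NC, 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= qlen; ++i) {
    for (int j = 1; j <= tlen; ++j) {
      size_t id = i * W + j;
      double eOpen = H[id - 1] - gapOpen - gapExt, eExt = E[id - 1] - gapExt;
      E[id] = std::max(eOpen, eExt); tbE[id] = (eOpen >= eExt) ? 1 : 0;
      double fOpen = H[id - W] - gapOpen - gapExt, fExt = F[id - W] - gapExt;
      F[id] = std::max(fOpen, fExt); tbF[id] = (fOpen >= fExt) ? 1 : 0;
      double d = H[id - W - 1] + S(i - 1, j - 1);
      double h = max3(d, E[id], F[id]);
      unsigned char dir = 0;
      if (h > 0.0) {
        if (h == d) dir = 1; else if (h == E[id]) dir = 2; else dir = 3;
      } else h = 0.0;
      H[id] = h; tbH[id] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> qp, tp;
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    size_t id = i * W + j;
    if (state == 0) {
      unsigned char dir = tbH[id];
      if (dir == 0) break;
      if (dir == 1) { qp.push_back(i); tp.push_back(j); --i; --j; }
      else if (dir == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (tbE[id]) state = 0;
      --j;
    } else {
      if (tbF[id]) state = 0;
      --i;
    }
  }
  std::reverse(qp.begin(), qp.end());
  std::reverse(tp.begin(), tp.end());
  IntegerMatrix pairs(qp.size(), 2);
  for (size_t k = 0; k < qp.size(); ++k) { pairs(k, 0) = qp[k]; pairs(k, 1) = tp[k]; }
  return List::create(_["score"] = best, _["pairs"] = pairs,
                      _["qstart"] = qp.empty() ? NA_INTEGER : qp.front(),
                      _["qend"] = qp.empty() ? NA_INTEGER : qp.back(),
                      _["tstart"] = tp.empty() ? NA_INTEGER : tp.front(),
                      _["tend"] = tp.empty() ? NA_INTEGER : tp.back());
}
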