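#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <memory>
using namespace Rcpp;

// GTR+I+G pruning engine on unrooted (or rooted) binary trees, organised as
// directed-edge message passing so that the same cached quantities serve the
// plain likelihood, per-edge branch-length optimisation, NNI candidate
// scoring and stepwise-addition placement scoring.
//
// Conventions:
//  - edge matrix is 1-based (ape); node nTip+1 is the traversal root.
//  - tip states are 4-bit IUPAC masks (A=1, C=2, G=4, T=8; N/- = 15).
//  - per-site likelihood: pinv * L_inv + (1-pinv) * mean over gamma
//    categories; L_inv = sum_s pi_s * [every tip mask contains s].
//  - messages m_{x->y}[i] = sum_j P(t_e)[i][j] * F_{x\y}[j]; valid for
//    time-reversible models evaluated from any vantage node.

struct SubModel {
  double U[16], Uinv[16], lambda[4], pi[4];
  std::vector<double> rates;
  double pinv, mult;
};

struct Engine {
  int nTip, nNode, nEdge, root, k, nPat, nSub;
  std::vector<int> e1, e2;          // 0-based node ids per edge
  std::vector<double> blen;
  std::vector<std::vector<int>> nbr, nbrEdge; // adjacency per node
  std::vector<int> parent, parentEdge, postorder; // rooted bookkeeping
  std::vector<SubModel> sub;
  const int* tip;                   // nTip x nPat masks (column-major)
  int tipNrow;
  std::vector<double> w;
  std::vector<int> subsetOf;        // per pattern, 0-based
  // message buffers left uninitialised on allocation (every slot is written
  // by a toward/away pass before any read)
  std::unique_ptr<double[]> msg;    // nDir * nPat * k * 4
  std::unique_ptr<double[]> clog;   // nDir * nPat
  std::vector<double> linv;         // per pattern

  inline int did(int e, int towardNode) const {
    // direction index: 0 flows toward e1, 1 toward e2
    return 2 * e + (towardNode == e2[e] ? 1 : 0);
  }
  inline double* M(int d) { return &msg[(size_t)d * nPat * k * 4]; }
  inline double* CL(int d) { return &clog[(size_t)d * nPat]; }

  void buildP(int s, double t, std::vector<double>& P) {
    // P: k * 16, row-major per category
    const SubModel& m = sub[s];
    for (int c = 0; c < k; ++c) {
      double el[4];
      double eff = t * m.mult * m.rates[c];
      for (int l = 0; l < 4; ++l) el[l] = std::exp(m.lambda[l] * eff);
      double* Pc = &P[c * 16];
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          double v = 0;
          for (int l = 0; l < 4; ++l) v += m.U[i * 4 + l] * el[l] * m.Uinv[l * 4 + j];
          Pc[i * 4 + j] = v > 0 ? v : 0;
        }
    }
  }

  // F_{x\y} for pattern p into buffer f (k*4); returns accumulated clog
  double gatherF(int x, int y, int p, double* f) {
    if (x < nTip) {
      int mask = tip[p * tipNrow + x];
      for (int c = 0; c < k; ++c)
        for (int s = 0; s < 4; ++s) f[c * 4 + s] = (mask >> s) & 1;
      return 0.0;
    }
    for (int i = 0; i < k * 4; ++i) f[i] = 1.0;
    double cl = 0.0;
    const std::vector<int>& nb = nbr[x];
    for (size_t a = 0; a < nb.size(); ++a) {
      if (nb[a] == y) continue;
      int d = did(nbrEdge[x][a], x);
      const double* mm = M(d) + (size_t)p * k * 4;
      for (int i = 0; i < k * 4; ++i) f[i] *= mm[i];
      cl += CL(d)[p];
    }
    return cl;
  }

  // per-mask message table for a pendant (tip) edge: tab[mask][c*4+i] =
  // sum_{j in mask} P_c[i][j], pre-scaled by its own maximum
  void buildTipTable(const std::vector<double>& P, double* tab, double* tabLog) {
    for (int m = 0; m < 16; ++m) {
      double* tm = tab + m * k * 4;
      double mx = 0.0;
      for (int c = 0; c < k; ++c) {
        const double* Pc = &P[c * 16];
        for (int i = 0; i < 4; ++i) {
          double v = 0.0;
          for (int j = 0; j < 4; ++j) if ((m >> j) & 1) v += Pc[i * 4 + j];
          tm[c * 4 + i] = v;
          if (v > mx) mx = v;
        }
      }
      if (mx <= 0 || !R_FINITE(mx)) mx = 1e-300;
      double inv = 1.0 / mx;
      for (int i = 0; i < k * 4; ++i) tm[i] *= inv;
      tabLog[m] = std::log(mx);
    }
  }

  void computeMessage(int e, int x, int y) {
    int d = did(e, y);
    std::vector<double> P(k * 16);
    std::vector<double> f(k * 4);
    double* out = M(d);
    double* cl = CL(d);
    int curSub = -1;
    if (x < nTip) {
      // pendant edge: message depends only on the tip mask -> table lookup
      std::vector<double> tab(16 * k * 4);
      std::vector<double> tabLog(16);
      int k4 = k * 4;
      for (int p = 0; p < nPat; ++p) {
        int s = subsetOf[p];
        if (s != curSub) {
          buildP(s, blen[e], P);
          buildTipTable(P, tab.data(), tabLog.data());
          curSub = s;
        }
        int mask = tip[p * tipNrow + x];
        std::copy(&tab[mask * k4], &tab[mask * k4] + k4, out + (size_t)p * k4);
        cl[p] = tabLog[mask];
      }
      return;
    }
    for (int p = 0; p < nPat; ++p) {
      int s = subsetOf[p];
      if (s != curSub) { buildP(s, blen[e], P); curSub = s; }
      double upstream = gatherF(x, y, p, f.data());
      double* o = out + (size_t)p * k * 4;
      double mx = 0.0;
      for (int c = 0; c < k; ++c) {
        const double* Pc = &P[c * 16];
        for (int i = 0; i < 4; ++i) {
          double v = Pc[i * 4 + 0] * f[c * 4 + 0] + Pc[i * 4 + 1] * f[c * 4 + 1]
                   + Pc[i * 4 + 2] * f[c * 4 + 2] + Pc[i * 4 + 3] * f[c * 4 + 3];
          o[c * 4 + i] = v;
          if (v > mx) mx = v;
        }
      }
      if (mx <= 0 || !R_FINITE(mx)) mx = 1e-300;
      double inv = 1.0 / mx;
      for (int i = 0; i < k * 4; ++i) o[i] *= inv;
      cl[p] = std::log(mx) + upstream;
    }
  }

  void towardRootPass() {
    for (int idx = (int)postorder.size() - 1; idx >= 0; --idx) {
      int x = postorder[idx]; // postorder stored root-first; reverse = children first
      if (x == root) continue;
      computeMessage(parentEdge[x], x, parent[x]);
    }
  }
  void awayRootPass() {
    for (size_t idx = 0; idx < postorder.size(); ++idx) {
      int x = postorder[idx]; // root-first (pre-order)
      const std::vector<int>& nb = nbr[x];
      for (size_t a = 0; a < nb.size(); ++a)
        if (x == root || nb[a] != parent[x])
          computeMessage(nbrEdge[x][a], x, nb[a]);
    }
  }

  void computeLinv(const int* extraMask) {
    linv.assign(nPat, 0.0);
    for (int p = 0; p < nPat; ++p) {
      const double* pi = sub[subsetOf[p]].pi;
      int both = 15;
      for (int t = 0; t < nTip; ++t) both &= tip[p * tipNrow + t];
      if (extraMask) both &= extraMask[p];
      double v = 0;
      for (int s = 0; s < 4; ++s) if ((both >> s) & 1) v += pi[s];
      linv[p] = v;
    }
  }

  // site log-likelihood from raw category sums and total scaling
  inline double siteLog(int p, double rawSum, double S) const {
    const SubModel& m = sub[subsetOf[p]];
    double varTerm = std::log((1.0 - m.pinv) * rawSum / k) + S;
    if (m.pinv <= 0 || linv[p] <= 0) return varTerm;
    double invTerm = std::log(m.pinv * linv[p]);
    double hi = std::max(varTerm, invTerm);
    return hi + std::log(std::exp(varTerm - hi) + std::exp(invTerm - hi));
  }

  double loglikAtRoot() {
    std::vector<double> f(k * 4);
    double total = 0.0;
    for (int p = 0; p < nPat; ++p) {
      double cl = gatherF(root, -1, p, f.data());
      const double* pi = sub[subsetOf[p]].pi;
      double raw = 0.0;
      for (int c = 0; c < k; ++c)
        for (int s = 0; s < 4; ++s) raw += pi[s] * f[c * 4 + s];
      total += w[p] * siteLog(p, raw, cl);
    }
    return total;
  }

  // as edgeLoglik below, but over pre-gathered endpoint partials Fa/Fb and
  // their joint scaling Cl; only the edge's P matrices depend on t, so a
  // 1-D optimiser can call this cheaply
  double edgeLoglikCached(double t, const double* Fa, const double* Fb,
                          const double* Cl, std::vector<double>& P) {
    double total = 0.0;
    int curSub = -1;
    int k4 = k * 4;
    for (int p = 0; p < nPat; ++p) {
      int s = subsetOf[p];
      if (s != curSub) { buildP(s, t, P); curSub = s; }
      const double* pi = sub[s].pi;
      const double* fa = Fa + (size_t)p * k4;
      const double* fb = Fb + (size_t)p * k4;
      double raw = 0.0;
      for (int c = 0; c < k; ++c) {
        const double* Pc = &P[c * 16];
        for (int i = 0; i < 4; ++i) {
          double pm = Pc[i * 4 + 0] * fb[c * 4 + 0] + Pc[i * 4 + 1] * fb[c * 4 + 1]
                    + Pc[i * 4 + 2] * fb[c * 4 + 2] + Pc[i * 4 + 3] * fb[c * 4 + 3];
          raw += pi[i] * fa[c * 4 + i] * pm;
        }
      }
      total += w[p] * siteLog(p, raw, Cl[p]);
    }
    return total;
  }

  // log-likelihood as a function of length t on edge e, using cached
  // messages on both sides (assumed current)
  double edgeLoglik(int e, double t) {
    int a = e1[e], b = e2[e];
    std::vector<double> P(k * 16), fa(k * 4), fb(k * 4);
    double total = 0.0;
    int curSub = -1;
    for (int p = 0; p < nPat; ++p) {
      int s = subsetOf[p];
      if (s != curSub) { buildP(s, t, P); curSub = s; }
      double ca = gatherF(a, b, p, fa.data());
      double cb = gatherF(b, a, p, fb.data());
      const double* pi = sub[s].pi;
      double raw = 0.0;
      for (int c = 0; c < k; ++c) {
        const double* Pc = &P[c * 16];
        for (int i = 0; i < 4; ++i) {
          double pm = Pc[i * 4 + 0] * fb[c * 4 + 0] + Pc[i * 4 + 1] * fb[c * 4 + 1]
                    + Pc[i * 4 + 2] * fb[c * 4 + 2] + Pc[i * 4 + 3] * fb[c * 4 + 3];
          raw += pi[i] * fa[c * 4 + i] * pm;
        }
      }
      total += w[p] * siteLog(p, raw, ca + cb);
    }
    return total;
  }
};

static void parseModels(List models, Engine& eng) {
  eng.nSub = models.size();
  eng.sub.resize(eng.nSub);
  for (int s = 0; s < eng.nSub; ++s) {
    List m = models[s];
    NumericMatrix U = m["U"], Uinv = m["Uinv"];
    NumericVector lam = m["lambda"], pi = m["pi"], rates = m["rates"];
    SubModel& sm = eng.sub[s];
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) { sm.U[i * 4 + j] = U(i, j); sm.Uinv[i * 4 + j] = Uinv(i, j); }
    for (int i = 0; i < 4; ++i) { sm.lambda[i] = lam[i]; sm.pi[i] = pi[i]; }
    sm.rates.assign(rates.begin(), rates.end());
    sm.pinv = as<double>(m["pinv"]);
    sm.mult = m.containsElementNamed("mult") ? as<double>(m["mult"]) : 1.0;
  }
}

static void buildEngine(Engine& eng, IntegerMatrix edge, int nTip,
                        NumericVector blen, IntegerMatrix tip, NumericVector w,
                        IntegerVector subset, List models, bool allocMsg) {
  eng.nTip = nTip;
  eng.nEdge = edge.nrow();
  eng.nPat = tip.ncol();
  eng.tip = tip.begin();
  eng.tipNrow = tip.nrow();
  eng.w.assign(w.begin(), w.end());
  eng.subsetOf.assign(subset.begin(), subset.end());
  parseModels(models, eng);
  eng.k = eng.sub[0].rates.size();
  int mx = 0;
  eng.e1.resize(eng.nEdge); eng.e2.resize(eng.nEdge);
  eng.blen.assign(blen.begin(), blen.end());
  for (int e = 0; e < eng.nEdge; ++e) {
    eng.e1[e] = edge(e, 0) - 1; eng.e2[e] = edge(e, 1) - 1;
    mx = std::max(mx, std::max(eng.e1[e], eng.e2[e]));
  }
  eng.nNode = mx + 1;
  eng.root = nTip; // node nTip+1, 0-based
  eng.nbr.assign(eng.nNode, {});
  eng.nbrEdge.assign(eng.nNode, {});
  for (int e = 0; e < eng.nEdge; ++e) {
    eng.nbr[eng.e1[e]].push_back(eng.e2[e]); eng.nbrEdge[eng.e1[e]].push_back(e);
    eng.nbr[eng.e2[e]].push_back(eng.e1[e]); eng.nbrEdge[eng.e2[e]].push_back(e);
  }
  // pre-order (root first) via DFS
  eng.parent.assign(eng.nNode, -1);
  eng.parentEdge.assign(eng.nNode, -1);
  eng.postorder.clear();
  std::vector<int> stack = {eng.root};
  while (!stack.empty()) {
    int x = stack.back(); stack.pop_back();
    eng.postorder.push_back(x);
    for (size_t a = 0; a < eng.nbr[x].size(); ++a) {
      int y = eng.nbr[x][a];
      if (y == eng.parent[x]) continue;
      eng.parent[y] = x; eng.parentEdge[y] = eng.nbrEdge[x][a];
      stack.push_back(y);
    }
  }
  if (allocMsg) {
    eng.msg.reset(new double[(size_t)2 * eng.nEdge * eng.nPat * eng.k * 4]);
    eng.clog.reset(new double[(size_t)2 * eng.nEdge * eng.nPat]);
  }
  eng.computeLinv(nullptr);
}

// Bounded 1-D maximiser (golden section with parabolic steps)
template <typename F>
static double brentMax(F f, double a, double b, double tol, int maxit, double& fx) {
  const double gold = 0.3819660112501051;
  double x = a + gold * (b - a), wp = x, v = x;
  fx = f(x);
  double fw = fx, fv = fx, d = 0, ep = 0;
  for (int it = 0; it < maxit; ++it) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10, tol2 = 2 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    double dd = 0; bool useGold = true;
    if (std::fabs(ep) > tol1) {
      double r = (x - wp) * (fx - fv), q = (x - v) * (fx - fw);
      double pp = (x - v) * q - (x - wp) * r;
      q = 2 * (q - r);
      if (q > 0) pp = -pp;
      q = std::fabs(q);
      double etmp = ep; ep = d;
      if (std::fabs(pp) < std::fabs(0.5 * q * etmp) && pp > q * (a - x) && pp < q * (b - x)) {
        dd = pp / q; useGold = false;
        double u = x + dd;
        if (u - a < tol2 || b - u < tol2) dd = (xm > x) ? tol1 : -tol1;
      }
    }
    if (useGold) { ep = (x >= xm) ? a - x : b - x; dd = gold * ep; }
    d = dd;
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu >= fx) {
      if (u >= x) a = x; else b = x;
      v = wp; fv = fw; wp = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu >= fw || wp == x) { v = wp; fv = fw; wp = u; fw = fu; }
      else if (fu >= fv || v == x || v == wp) { v = u; fv = fu; }
    }
  }
  return x;
}

// [[Rcpp::export(name = ".phylo_loglik")]]
List phylo_loglik(IntegerMatrix edge, int nTip, NumericVector blen,
                  IntegerMatrix tip, NumericVector w, IntegerVector subset,
                  List models, bool siteLnl = false) {
  Engine eng;
  buildEngine(eng, edge, nTip, blen, tip, w, subset, models, true);
  eng.towardRootPass();
  double ll = eng.loglikAtRoot();
  if (!siteLnl) return List::create(_["loglik"] = ll);
  // recompute per-site values
  NumericVector s(eng.nPat);
  std::vector<double> f(eng.k * 4);
  for (int p = 0; p < eng.nPat; ++p) {
    double cl = eng.gatherF(eng.root, -1, p, f.data());
    const double* pi = eng.sub[eng.subsetOf[p]].pi;
    double raw = 0.0;
    for (int c = 0; c < eng.k; ++c)
      for (int st = 0; st < 4; ++st) raw += pi[st] * f[c * 4 + st];
    s[p] = eng.siteLog(p, raw, cl);
  }
  return List::create(_["loglik"] = ll, _["sitelnl"] = s);
}

// [[Rcpp::export(name = ".phylo_optimize_blens")]]
List phylo_optimize_blens(IntegerMatrix edge, int nTip, NumericVector blen,
                          IntegerMatrix tip, NumericVector w, IntegerVector subset,
                          List models, int nsweeps = 3, double tol = 1e-4,
                          double minlen = 1e-8, double maxlen = 10.0,
                          double brentTol = 2e-3, int brentMaxit = 40) {
  Engine eng;
  buildEngine(eng, edge, nTip, blen, tip, w, subset, models, true);
  eng.towardRootPass();
  double prev = eng.loglikAtRoot();
  double lo = std::log(minlen), hi = std::log(maxlen);
  std::vector<double> bestBlen = eng.blen;
  double bestLl = prev;
  int k4 = eng.k * 4;
  std::vector<double> Fa((size_t)eng.nPat * k4), Fb((size_t)eng.nPat * k4);
  std::vector<double> Cl(eng.nPat), P(eng.k * 16);
  for (int sw = 0; sw < nsweeps; ++sw) {
    eng.towardRootPass();
    eng.awayRootPass();
    for (int e = 0; e < eng.nEdge; ++e) {
      int a = eng.e1[e], b = eng.e2[e];
      for (int p = 0; p < eng.nPat; ++p) {
        double ca = eng.gatherF(a, b, p, &Fa[(size_t)p * k4]);
        double cb = eng.gatherF(b, a, p, &Fb[(size_t)p * k4]);
        Cl[p] = ca + cb;
      }
      double fOld = eng.edgeLoglikCached(eng.blen[e], Fa.data(), Fb.data(),
                                         Cl.data(), P);
      double fNew;
      double xb = brentMax([&](double x) {
        return eng.edgeLoglikCached(std::exp(x), Fa.data(), Fb.data(),
                                    Cl.data(), P);
      }, lo, hi, brentTol, brentMaxit, fNew);
      if (fNew > fOld) eng.blen[e] = std::exp(xb);
    }
    eng.towardRootPass();
    double ll = eng.loglikAtRoot();
    if (ll > bestLl) { bestLl = ll; bestBlen = eng.blen; }
    if (ll - prev < tol && sw > 0) break;
    prev = ll;
  }
  return List::create(_["blen"] = NumericVector(bestBlen.begin(), bestBlen.end()),
                      _["loglik"] = bestLl);
}

// Evaluate, for every internal edge, the current configuration and the two
// NNI rearrangements (branch lengths held fixed; subtrees keep their own
// pendant lengths). Returns node ids needed to apply a swap in R.
// [[Rcpp::export(name = ".phylo_nni_eval")]]
DataFrame phylo_nni_eval(IntegerMatrix edge, int nTip, NumericVector blen,
                         IntegerMatrix tip, NumericVector w, IntegerVector subset,
                         List models) {
  Engine eng;
  buildEngine(eng, edge, nTip, blen, tip, w, subset, models, true);
  eng.towardRootPass();
  eng.awayRootPass();
  std::vector<int> edgeIdx, uN, vN, sN, cN, dN;
  std::vector<double> l0, l1, l2;
  std::vector<double> P(eng.k * 16);
  for (int e = 0; e < eng.nEdge; ++e) {
    int u = eng.e1[e], v = eng.e2[e];
    if (eng.parent[u] == v) std::swap(u, v); // ensure u = parent side
    if (v < eng.nTip || u < eng.nTip) continue; // need both internal
    // children of v (neighbors except u)
    std::vector<int> vc, vcE;
    for (size_t a = 0; a < eng.nbr[v].size(); ++a)
      if (eng.nbr[v][a] != u) { vc.push_back(eng.nbr[v][a]); vcE.push_back(eng.nbrEdge[v][a]); }
    if (vc.size() != 2) continue;
    // sibling S at u and the residual product
    std::vector<int> others, othersE;
    for (size_t a = 0; a < eng.nbr[u].size(); ++a)
      if (eng.nbr[u][a] != v) { others.push_back(eng.nbr[u][a]); othersE.push_back(eng.nbrEdge[u][a]); }
    if (others.empty()) continue;
    int S = others[0];
    int dS = eng.did(othersE[0], u);
    int dC = eng.did(vcE[0], v), dD = eng.did(vcE[1], v);
    // residual: messages into u from others[1..] (for the pseudo-root) —
    // for a non-root u, others[] already includes the parent of u.
    std::vector<int> resDirs;
    for (size_t a = 1; a < others.size(); ++a) resDirs.push_back(eng.did(othersE[a], u));
    double ll0 = 0, ll1 = 0, ll2 = 0;
    int curSub = -1;
    for (int p = 0; p < eng.nPat; ++p) {
      int s = eng.subsetOf[p];
      if (s != curSub) { eng.buildP(s, eng.blen[e], P); curSub = s; }
      const double* pi = eng.sub[s].pi;
      const double* mS = eng.M(dS) + (size_t)p * eng.k * 4;
      const double* mC = eng.M(dC) + (size_t)p * eng.k * 4;
      const double* mD = eng.M(dD) + (size_t)p * eng.k * 4;
      double Sp = eng.CL(dS)[p] + eng.CL(dC)[p] + eng.CL(dD)[p];
      double raw0 = 0, raw1 = 0, raw2 = 0;
      for (int c = 0; c < eng.k; ++c) {
        const double* Pc = &P[c * 16];
        double res[4] = {1, 1, 1, 1};
        for (size_t rI = 0; rI < resDirs.size(); ++rI) {
          const double* mr = eng.M(resDirs[rI]) + (size_t)p * eng.k * 4;
          for (int i = 0; i < 4; ++i) res[i] *= mr[c * 4 + i];
        }
        double hv0[4], hv1[4], hv2[4];
        for (int j = 0; j < 4; ++j) {
          hv0[j] = mC[c * 4 + j] * mD[c * 4 + j];
          hv1[j] = mS[c * 4 + j] * mD[c * 4 + j];
          hv2[j] = mS[c * 4 + j] * mC[c * 4 + j];
        }
        for (int i = 0; i < 4; ++i) {
          double base = pi[i] * res[i];
          double pm0 = 0, pm1 = 0, pm2 = 0;
          for (int j = 0; j < 4; ++j) {
            double pij = Pc[i * 4 + j];
            pm0 += pij * hv0[j]; pm1 += pij * hv1[j]; pm2 += pij * hv2[j];
          }
          raw0 += base * mS[c * 4 + i] * pm0;
          raw1 += base * mC[c * 4 + i] * pm1;
          raw2 += base * mD[c * 4 + i] * pm2;
        }
      }
      for (size_t rI = 0; rI < resDirs.size(); ++rI) Sp += eng.CL(resDirs[rI])[p];
      ll0 += eng.w[p] * eng.siteLog(p, raw0, Sp);
      ll1 += eng.w[p] * eng.siteLog(p, raw1, Sp);
      ll2 += eng.w[p] * eng.siteLog(p, raw2, Sp);
    }
    edgeIdx.push_back(e + 1); uN.push_back(u + 1); vN.push_back(v + 1);
    sN.push_back(S + 1); cN.push_back(vc[0] + 1); dN.push_back(vc[1] + 1);
    l0.push_back(ll0); l1.push_back(ll1); l2.push_back(ll2);
  }
  return DataFrame::create(_["edge"] = edgeIdx, _["u"] = uN, _["v"] = vN,
                           _["S"] = sN, _["C"] = cN, _["D"] = dN,
                           _["lnl_cur"] = l0, _["lnl_swapSC"] = l1,
                           _["lnl_swapSD"] = l2);
}

// Score attaching a new tip (pendant length tNew) at the midpoint of every
// edge of the current tree. The invariant-class term uses the augmented tip
// set (newMask per pattern).
// [[Rcpp::export(name = ".phylo_placement")]]
NumericVector phylo_placement(IntegerMatrix edge, int nTip, NumericVector blen,
                              IntegerMatrix tip, NumericVector w, IntegerVector subset,
                              List models, IntegerVector newMask, double tNew) {
  Engine eng;
  buildEngine(eng, edge, nTip, blen, tip, w, subset, models, true);
  eng.computeLinv(newMask.begin());
  eng.towardRootPass();
  eng.awayRootPass();
  NumericVector out(eng.nEdge);
  int k4 = eng.k * 4;
  // the new tip's message depends only on (subset, mask): precompute tables
  std::vector<double> Pt(eng.k * 16);
  std::vector<double> tTab((size_t)eng.nSub * 16 * k4);
  for (int s = 0; s < eng.nSub; ++s) {
    eng.buildP(s, tNew, Pt);
    for (int m = 0; m < 16; ++m) {
      double* tm = &tTab[((size_t)s * 16 + m) * k4];
      for (int c = 0; c < eng.k; ++c)
        for (int i = 0; i < 4; ++i) {
          double v = 0.0;
          for (int j = 0; j < 4; ++j)
            if ((m >> j) & 1) v += Pt[c * 16 + i * 4 + j];
          tm[c * 4 + i] = v;
        }
    }
  }
  std::vector<double> Pa(eng.k * 16), fa(eng.k * 4), fb(eng.k * 4);
  for (int e = 0; e < eng.nEdge; ++e) {
    int a = eng.e1[e], b = eng.e2[e];
    double ll = 0.0;
    int curSub = -1;
    for (int p = 0; p < eng.nPat; ++p) {
      int s = eng.subsetOf[p];
      if (s != curSub) {
        eng.buildP(s, eng.blen[e] * 0.5, Pa);
        curSub = s;
      }
      double ca = eng.gatherF(a, b, p, fa.data());
      double cb = eng.gatherF(b, a, p, fb.data());
      const double* mTv = &tTab[((size_t)s * 16 + newMask[p]) * k4];
      const double* pi = eng.sub[s].pi;
      double raw = 0.0;
      for (int c = 0; c < eng.k; ++c) {
        const double* Pc = &Pa[c * 16];
        for (int i = 0; i < 4; ++i) {
          double mA = 0, mB = 0;
          for (int j = 0; j < 4; ++j) {
            mA += Pc[i * 4 + j] * fa[c * 4 + j];
            mB += Pc[i * 4 + j] * fb[c * 4 + j];
          }
          raw += pi[i] * mA * mB * mTv[c * 4 + i];
        }
      }
      ll += eng.w[p] * eng.siteLog(p, raw, ca + cb);
    }
    out[e] = ll;
  }
  return out;
}
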