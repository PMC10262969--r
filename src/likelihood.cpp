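// Felsenstein pruning under a reversible substitution model with discrete
// rate categories, plus coordinate-wise Brent optimization of branch lengths.
//
// Conventions shared with the R callers:
//  * nodes are 0-based; tips are 0..ntip-1; edges arrive in postorder as
//    (parent, child) pairs so a single forward sweep fills the conditional
//    (tip-ward) partials and a reverse sweep fills the root-ward partials;
//  * the model is passed as the spectral decomposition of the rate matrix
//    Q = evec %*% diag(eval) %*% ievec, so P(t, r) = evec diag(exp(eval t r)) ievec;
//  * rate categories carry their own weights (an invariant class is just a
//    category with rate 0), and tip partials encode ambiguity as 0/1 masks.
//
// Trees handled here are small (<= ~16 tips), so no per-node rescaling is
// performed; per-site likelihoods stay far above double underflow.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int ns;                       // number of states
  std::vector<double> pi;
  std::vector<double> eval;     // eigenvalues of Q
  std::vector<double> evec;     // ns*ns row-major
  std::vector<double> ievec;    // ns*ns row-major
  std::vector<double> catRates;
  std::vector<double> catWeights;
};

Model unpackModel(const NumericVector& pi, const NumericVector& eval,
                  const NumericMatrix& evec, const NumericMatrix& ievec,
                  const NumericVector& catRates, const NumericVector& catWeights) {
  Model m;
  m.ns = pi.size();
  m.pi.assign(pi.begin(), pi.end());
  m.eval.assign(eval.begin(), eval.end());
  m.catRates.assign(catRates.begin(), catRates.end());
  m.catWeights.assign(catWeights.begin(), catWeights.end());
  m.evec.resize(m.ns * m.ns);
  m.ievec.resize(m.ns * m.ns);
  for (int i = 0; i < m.ns; ++i)
    for (int j = 0; j < m.ns; ++j) {
      m.evec[i * m.ns + j] = evec(i, j);
      m.ievec[i * m.ns + j] = ievec(i, j);
    }
  return m;
}

// P(t*rate) into out (ns*ns row-major); ex is caller scratch of size ns
void transMat(const Model& m, double t, double rate, double* out, double* ex) {
  const int ns = m.ns;
  for (int k = 0; k < ns; ++k) ex[k] = std::exp(m.eval[k] * t * rate);
  for (int i = 0; i < ns; ++i) {
    for (int j = 0; j < ns; ++j) {
      double acc = 0.0;
      for (int k = 0; k < ns; ++k)
        acc += m.evec[i * ns + k] * ex[k] * m.ievec[k * ns + j];
      out[i * ns + j] = acc < 0.0 ? 0.0 : acc;  // clip eigen round-off
    }
  }
}

// Workspace for one tree: per category, per node, ns x npat arrays.
struct Work {
  int ns, npat, ncat, nnode, nedge, ntip, root;
  std::vector<int> ep, ec;               // edge parent/child (0-based)
  std::vector<double> len;
  // down[cat][node][state*npat + pat]: conditional likelihood of the subtree
  // below `node` (after multiplying child edge matrices into the node).
  std::vector<double> down;
  // msg[cat][edge][...]: P_e %*% down[child], i.e. the edge's contribution
  // as seen from the parent.
  std::vector<double> msg;
  // upb[cat][edge][...]: root-ward partial at the child end of the edge,
  // *before* crossing the edge (includes pi at the root).
  std::vector<double> upb;
  std::vector<double> tip;               // tip partials [tipnode][state*npat+pat]
  std::vector<double> wts;
  // preallocated scratch (the hot loops must not allocate)
  std::vector<double> P, ex, accP, up;

  inline double* D(int cat, int node) { return &down[(size_t)(cat * nnode + node) * ns * npat]; }
  inline double* M(int cat, int e) { return &msg[(size_t)(cat * nedge + e) * ns * npat]; }
  inline double* U(int cat, int e) { return &upb[(size_t)(cat * nedge + e) * ns * npat]; }
  inline const double* T(int tipnode) const { return &tip[(size_t)tipnode * ns * npat]; }
};

Work makeWork(const IntegerMatrix& edge, const NumericVector& edgeLen, int ntip,
              int nnode, int root, const NumericVector& tipPart,
              const NumericVector& weights, const Model& m) {
  Work w;
  w.ns = m.ns;
  w.ncat = m.catRates.size();
  w.npat = weights.size();
  w.nnode = nnode;
  w.nedge = edge.nrow();
  w.ntip = ntip;
  w.root = root;
  w.ep.resize(w.nedge);
  w.ec.resize(w.nedge);
  w.len.assign(edgeLen.begin(), edgeLen.end());
  for (int e = 0; e < w.nedge; ++e) {
    w.ep[e] = edge(e, 0);
    w.ec[e] = edge(e, 1);
  }
  w.down.assign((size_t)w.ncat * nnode * w.ns * w.npat, 1.0);
  w.msg.assign((size_t)w.ncat * w.nedge * w.ns * w.npat, 0.0);
  w.upb.assign((size_t)w.ncat * w.nedge * w.ns * w.npat, 0.0);
  w.tip.assign(tipPart.begin(), tipPart.end());
  w.wts.assign(weights.begin(), weights.end());
  w.P.assign(w.ns * w.ns, 0.0);
  w.ex.assign(w.ns, 0.0);
  w.accP.assign(w.npat, 0.0);
  w.up.assign((size_t)w.ncat * nnode * w.ns * w.npat, 0.0);
  return w;
}

// Full tip-ward pass; fills down and msg for every category.
void downPass(Work& w, const Model& m) {
  const int ns = w.ns, npat = w.npat;
  double* P = w.P.data();
  std::fill(w.down.begin(), w.down.end(), 1.0);
  for (int cat = 0; cat < w.ncat; ++cat) {
    // seed tips
    for (int t = 0; t < w.ntip; ++t) {
      double* d = w.D(cat, t);
      const double* tp = w.T(t);
      std::copy(tp, tp + ns * npat, d);
    }
    for (int e = 0; e < w.nedge; ++e) {
      transMat(m, w.len[e], m.catRates[cat], P, w.ex.data());
      const double* dc = w.D(cat, w.ec[e]);
      double* dp = w.D(cat, w.ep[e]);
      double* me = w.M(cat, e);
      for (int i = 0; i < ns; ++i) {
        for (int p = 0; p < npat; ++p) {
          double acc = 0.0;
          for (int j = 0; j < ns; ++j) acc += P[i * ns + j] * dc[j * npat + p];
          me[i * npat + p] = acc;
        }
      }
      for (int i = 0; i < ns; ++i)
        for (int p = 0; p < npat; ++p) dp[i * npat + p] *= me[i * npat + p];
    }
  }
}

// Root-ward pass; requires downPass results. Fills upb per edge.
void upPass(Work& w, const Model& m) {
  const int ns = w.ns, npat = w.npat;
  double* P = w.P.data();
  // up[node]: root-ward partial at the node (after crossing its parent edge);
  // root gets pi.
  std::vector<double>& up = w.up;
  for (int cat = 0; cat < w.ncat; ++cat) {
    double* ur = &up[(size_t)(cat * w.nnode + w.root) * ns * npat];
    for (int i = 0; i < ns; ++i)
      for (int p = 0; p < npat; ++p) ur[i * npat + p] = m.pi[i];
    for (int e = w.nedge - 1; e >= 0; --e) {  // reverse postorder = preorder
      const int par = w.ep[e], ch = w.ec[e];
      const double* upar = &up[(size_t)(cat * w.nnode + par) * ns * npat];
      const double* dpar = w.D(cat, par);
      const double* me = w.M(cat, e);
      double* ub = w.U(cat, e);
      // product over sibling messages = down[parent] / msg[e]; guard 0/0 by
      // recomputing as explicit division only when msg > 0, else rebuild.
      for (int i = 0; i < ns; ++i) {
        for (int p = 0; p < npat; ++p) {
          double sib;
          double mv = me[i * npat + p];
          if (mv > 0.0) {
            sib = dpar[i * npat + p] / mv;
          } else {
            // rare: rebuild product excluding e
            sib = 1.0;
            for (int e2 = 0; e2 < w.nedge; ++e2) {
              if (e2 == e || w.ep[e2] != par) continue;
              sib *= w.M(cat, e2)[i * npat + p];
            }
            // tip contribution never multiplies into an internal parent's
            // down except via msg, and parent may itself be a tip only in
            // 2-taxon trees rooted at a tip; include its own tip mask then.
            if (par < w.ntip) sib *= w.T(par)[i * npat + p];
          }
          ub[i * npat + p] = upar[i * npat + p] * sib;
        }
      }
      // up[child] = t(P_e) %*% upb
      transMat(m, w.len[e], m.catRates[cat], P, w.ex.data());
      double* uch = &up[(size_t)(cat * w.nnode + ch) * ns * npat];
      for (int j = 0; j < ns; ++j) {
        for (int p = 0; p < npat; ++p) {
          double acc = 0.0;
          for (int i = 0; i < ns; ++i) acc += P[i * ns + j] * ub[i * npat + p];
          uch[j * npat + p] = acc;
        }
      }
    }
  }
}

// NOTE: downPass multiplies tip partials into down[tip]; if the root is a tip
// (2-taxon trees handled in R by rooting at an internal node) this still works
// because down[root] then already includes the mask.

double rootLogLik(Work& w, const Model& m) {
  const int ns = w.ns, npat = w.npat;
  double lnL = 0.0;
  for (int p = 0; p < npat; ++p) {
    double Ls = 0.0;
    for (int cat = 0; cat < w.ncat; ++cat) {
      const double* dr = w.D(cat, w.root);
      double Lc = 0.0;
      for (int i = 0; i < ns; ++i) Lc += m.pi[i] * dr[i * npat + p];
      Ls += m.catWeights[cat] * Lc;
    }
    lnL += w.wts[p] * std::log(Ls);
  }
  return lnL;
}

// lnL as a function of one edge length, with F = upb (fixed) and G = down[child]
// (fixed): L_pat = sum_cat wcat sum_ij F_i P_ij(x) G_j.
double edgeLogLik(Work& w, const Model& m, int e, double x) {
  const int ns = w.ns, npat = w.npat;
  double* P = w.P.data();
  double* acc = w.accP.data();
  std::fill(acc, acc + npat, 0.0);
  for (int cat = 0; cat < w.ncat; ++cat) {
    transMat(m, x, m.catRates[cat], P, w.ex.data());
    const double* F = w.U(cat, e);
    const double* G = w.D(cat, w.ec[e]);
    const double wc = m.catWeights[cat];
    for (int p = 0; p < npat; ++p) {
      double Lc = 0.0;
      for (int i = 0; i < ns; ++i) {
        double inner = 0.0;
        for (int j = 0; j < ns; ++j) inner += P[i * ns + j] * G[j * npat + p];
        Lc += F[i * npat + p] * inner;
      }
      acc[p] += wc * Lc;
    }
  }
  double lnL = 0.0;
  for (int p = 0; p < npat; ++p) lnL += w.wts[p] * std::log(acc[p]);
  return lnL;
}

// Bounded Brent maximization of f on [a, b] (local minimizer of -f).
template <typename F>
double brentMax(F f, double a, double b, double tol, double* fbest) {
  const double gr = 0.3819660112501051;
  double x = a + gr * (b - a), v = x, u;
  double fx = -f(x), fv = fx, fw = fx;
  double d = 0.0, e = 0.0, wpt = x;
  for (int iter = 0; iter < 100; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - wpt) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double pp = (x - v) * q - (x - wpt) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) pp = -pp;
      q = std::fabs(q);
      double etmp = e;
      e = d;
      if (std::fabs(pp) < std::fabs(0.5 * q * etmp) && pp > q * (a - x) &&
          pp < q * (b - x)) {
        d = pp / q;
        u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm) ? a - x : b - x;
      d = gr * e;
    }
    u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = -f(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = wpt; fv = fw;
      wpt = x; fw = fx;
      x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || wpt == x) {
        v = wpt; fv = fw;
        wpt = u; fw = fu;
      } else if (fu <= fv || v == x || v == wpt) {
        v = u; fv = fu;
      }
    }
  }
  if (fbest) *fbest = -fx;
  return x;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_loglik")]]
double cpp_loglik(IntegerMatrix edge, NumericVector edgeLen, int ntip, int nnode,
                  int root, NumericVector tipPart, NumericVector weights,
                  NumericVector pi, NumericVector eval, NumericMatrix evec,
                  NumericMatrix ievec, NumericVector catRates,
                  NumericVector catWeights) {
  Model m = unpackModel(pi, eval, evec, ievec, catRates, catWeights);
  Work w = makeWork(edge, edgeLen, ntip, nnode, root, tipPart, weights, m);
  downPass(w, m);
  return rootLogLik(w, m);
}

// Per-pattern, per-category site likelihoods (category prior NOT applied).
// [[Rcpp::export(name = ".cpp_site_lik")]]
NumericMatrix cpp_site_lik(IntegerMatrix edge, NumericVector edgeLen, int ntip,
                           int nnode, int root, NumericVector tipPart,
                           NumericVector weights, NumericVector pi,
                           NumericVector eval, NumericMatrix evec,
                           NumericMatrix ievec, NumericVector catRates,
                           NumericVector catWeights) {
  Model m = unpackModel(pi, eval, evec, ievec, catRates, catWeights);
  Work w = makeWork(edge, edgeLen, ntip, nnode, root, tipPart, weights, m);
  downPass(w, m);
  NumericMatrix out(w.npat, w.ncat);
  for (int cat = 0; cat < w.ncat; ++cat) {
    const double* dr = w.D(cat, root);
    for (int p = 0; p < w.npat; ++p) {
      double Lc = 0.0;
      for (int i = 0; i < m.ns; ++i) Lc += m.pi[i] * dr[i * w.npat + p];
      out(p, cat) = Lc;
    }
  }
  return out;
}

// Coordinate-wise branch-length optimization: postorder sweeps, each edge
// maximized by bounded Brent with the rest of the tree held fixed.
// [[Rcpp::export(name = ".cpp_optimize_branches")]]
List cpp_optimize_branches(IntegerMatrix edge, NumericVector edgeLen, int ntip,
                           int nnode, int root, NumericVector tipPart,
                           NumericVector weights, NumericVector pi,
                           NumericVector eval, NumericMatrix evec,
                           NumericMatrix ievec, NumericVector catRates,
                           NumericVector catWeights, double minLen,
                           double maxLen, double relTol, int maxSweeps,
                           double brentTol) {
  Model m = unpackModel(pi, eval, evec, ievec, catRates, catWeights);
  Work w = makeWork(edge, edgeLen, ntip, nnode, root, tipPart, weights, m);
  downPass(w, m);
  double lnL = rootLogLik(w, m);
  int sweeps = 0;
  bool converged = false;
  for (; sweeps < maxSweeps; ++sweeps) {
    double prev = lnL;
    for (int e = 0; e < w.nedge; ++e) {
      downPass(w, m);
      upPass(w, m);
      double fbest;
      auto f = [&](double x) { return edgeLogLik(w, m, e, x); };
      double cur = f(w.len[e]);
      double xb = brentMax(f, minLen, maxLen, brentTol, &fbest);
      if (fbest > cur + 1e-12) w.len[e] = xb;
    }
    downPass(w, m);
    lnL = rootLogLik(w, m);
    double denom = std::fabs(prev) > 1.0 ? std::fabs(prev) : 1.0;
    if ((lnL - prev) / denom < relTol) {
      ++sweeps;
      converged = true;
      break;
    }
  }
  return List::create(_["lengths"] = NumericVector(w.len.begin(), w.len.end()),
                      _["loglik"] = lnL, _["sweeps"] = sweeps,
                      _["converged"] = converged);
}
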