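// Felsenstein pruning and exhaustive per-edge ML placement for JC69/HKY85.
// Site patterns are compressed internally; partial likelihoods carry
// per-pattern log scalers so deep trees do not underflow.

#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>

using namespace Rcpp;

// analytic HKY85 transition matrix (JC69 = kappa 1, equal frequencies),
// normalized to one expected substitution per site per unit branch length
static void pmatrix(double t, double kappa, const double* bf, double* P) {
  const double piR = bf[0] + bf[2], piY = bf[1] + bf[3];
  const double beta = 1.0 / (2.0 * (bf[0] * bf[1] + bf[0] * bf[3] +
                                    bf[1] * bf[2] + bf[2] * bf[3]) +
                             2.0 * kappa * (bf[0] * bf[2] + bf[1] * bf[3]));
  const double grp[4] = {piR, piY, piR, piY};
  const double e2 = std::exp(-beta * t);
  for (int j = 0; j < 4; ++j) {
    const double Aj = 1.0 + grp[j] * (kappa - 1.0);
    const double e3 = std::exp(-beta * t * Aj);
    for (int i = 0; i < 4; ++i) {
      double v;
      if (i == j) {
        v = bf[j] + bf[j] * (1.0 / grp[j] - 1.0) * e2 +
            ((grp[j] - bf[j]) / grp[j]) * e3;
      } else if ((i % 2) == (j % 2)) { // same purine/pyrimidine group
        v = bf[j] + bf[j] * (1.0 / grp[j] - 1.0) * e2 -
            (bf[j] / grp[j]) * e3;
      } else {
        v = bf[j] * (1.0 - e2);
      }
      P[i * 4 + j] = v;
    }
  }
}

struct Patterns {
  std::vector<int> codes;   // (ntaxa) x npat, column-major by pattern
  std::vector<double> wts;  // npat
  int npat;
};

// compress identical site columns; codes 0..3 = ACGT, 4 = missing
static Patterns compress(const IntegerMatrix& data) {
  const int ntaxa = data.nrow(), nsites = data.ncol();
  std::map<std::vector<int>, int> seen;
  Patterns out;
  out.npat = 0;
  std::vector<int> col(ntaxa);
  for (int s = 0; s < nsites; ++s) {
    for (int i = 0; i < ntaxa; ++i) col[i] = data(i, s);
    auto it = seen.find(col);
    if (it == seen.end()) {
      seen[col] = out.npat;
      for (int i = 0; i < ntaxa; ++i) out.codes.push_back(col[i]);
      out.wts.push_back(1.0);
      ++out.npat;
    } else {
      out.wts[it->second] += 1.0;
    }
  }
  return out;
}

struct TreeIdx {
  int ntip, nnode, root, nedge;
  std::vector<int> parent, child;       // per edge
  std::vector<double> elen;             // per edge
  std::vector<int> postorder;           // edge indices, children first
  std::vector<int> edge_above;          // node -> incoming edge (-1 root)
  std::vector<std::vector<int>> kids;   // node -> outgoing edge indices
};

static TreeIdx build_tree(const IntegerMatrix& edge, const NumericVector& elen,
                          int ntip) {
  TreeIdx T;
  T.ntip = ntip;
  T.nedge = edge.nrow();
  int maxn = 0;
  for (int e = 0; e < T.nedge; ++e) {
    T.parent.push_back(edge(e, 0) - 1);
    T.child.push_back(edge(e, 1) - 1);
    maxn = std::max(maxn, std::max(edge(e, 0), edge(e, 1)));
  }
  T.nnode = maxn;
  T.elen.assign(elen.begin(), elen.end());
  T.edge_above.assign(T.nnode, -1);
  T.kids.assign(T.nnode, {});
  for (int e = 0; e < T.nedge; ++e) {
    T.edge_above[T.child[e]] = e;
    T.kids[T.parent[e]].push_back(e);
  }
  T.root = -1;
  for (int n = ntip; n < T.nnode; ++n) {
    if (T.edge_above[n] == -1) T.root = n;
  }
  // postorder over edges via explicit stack
  std::vector<int> stack, order;
  stack.push_back(T.root);
  while (!stack.empty()) {
    int nd = stack.back(); stack.pop_back();
    for (int e : T.kids[nd]) {
      order.push_back(e);
      stack.push_back(T.child[e]);
    }
  }
  T.postorder.assign(order.rbegin(), order.rend());
  return T;
}

// down partials D[node][pat*4+x] with per-pattern log scalers
struct Partials {
  std::vector<std::vector<double>> D, scale;
};

static void down_pass(const TreeIdx& T, const Patterns& pat,
                      const std::vector<int>& taxon_of_tip, double kappa,
                      const double* bf, Partials& P) {
  const int np = pat.npat;
  P.D.assign(T.nnode, std::vector<double>());
  P.scale.assign(T.nnode, std::vector<double>(np, 0.0));
  const int ntaxa_in_codes = (int)pat.codes.size() / np;
  for (int n = 0; n < T.nnode; ++n) P.D[n].assign(np * 4, 1.0);
  for (int tip = 0; tip < T.ntip; ++tip) {
    const int tx = taxon_of_tip[tip];
    for (int s = 0; s < np; ++s) {
      const int c = pat.codes[(size_t)s * ntaxa_in_codes + tx];
      double* d = &P.D[tip][(size_t)s * 4];
      if (c < 4) {
        d[0] = d[1] = d[2] = d[3] = 0.0;
        d[c] = 1.0;
      }
    }
  }
  double Pm[16];
  for (int e : T.postorder) {
    const int ch = T.child[e], pa = T.parent[e];
    pmatrix(T.elen[e], kappa, bf, Pm);
    for (int s = 0; s < np; ++s) {
      const double* dc = &P.D[ch][(size_t)s * 4];
      double* dp = &P.D[pa][(size_t)s * 4];
      double mx = 0.0;
      double tmp[4];
      for (int x = 0; x < 4; ++x) {
        double acc = 0.0;
        for (int y = 0; y < 4; ++y) acc += Pm[x * 4 + y] * dc[y];
        tmp[x] = acc;
      }
      for (int x = 0; x < 4; ++x) {
        dp[x] *= tmp[x];
        if (dp[x] > mx) mx = dp[x];
      }
      P.scale[pa][s] += P.scale[ch][s];
      if (mx > 0 && mx < 1e-100) {
        for (int x = 0; x < 4; ++x) dp[x] /= mx;
        P.scale[pa][s] += std::log(mx);
      }
    }
  }
}

// [[Rcpp::export]]
double cpp_tree_loglik(IntegerMatrix edge, NumericVector elen, int ntip,
                       IntegerMatrix data, double kappa, NumericVector bf) {
  TreeIdx T = build_tree(edge, elen, ntip);
  Patterns pat = compress(data);
  std::vector<int> taxon_of_tip(ntip);
  for (int i = 0; i < ntip; ++i) taxon_of_tip[i] = i;
  Partials P;
  down_pass(T, pat, taxon_of_tip, kappa, bf.begin(), P);
  double lnl = 0.0;
  for (int s = 0; s < pat.npat; ++s) {
    const double* d = &P.D[T.root][(size_t)s * 4];
    double L = 0.0;
    for (int x = 0; x < 4; ++x) L += bf[x] * d[x];
    lnl += pat.wts[s] * (std::log(L) + P.scale[T.root][s]);
  }
  return lnl;
}

// golden-section maximization of f over [lo, hi]
template <typename F>
static double golden_max(F f, double lo, double hi, double tol, double* fbest) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = f(c), fd = f(d);
  while (b - a > tol) {
    if (fc > fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a); fc = f(c);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a); fd = f(d);
    }
  }
  double x = (a + b) / 2.0, fx = f(x);
  if (fc > fx) { x = c; fx = fc; }
  if (fd > fx) { x = d; fx = fd; }
  *fbest = fx;
  return x;
}

// Per-edge ML placement of a query on a fixed reference tree.
// data: (ntip + 1) x nsites codes; last row is the query.
// Returns per-edge optimal pendant length and log-likelihood.
// [[Rcpp::export]]
List cpp_place_query(IntegerMatrix edge, NumericVector elen, int ntip,
                     IntegerMatrix data, double kappa, NumericVector bf,
                     double pend_lo, double pend_hi, double tol) {
  TreeIdx T = build_tree(edge, elen, ntip);
  Patterns pat = compress(data);
  const double* bfp = bf.begin();
  const int np = pat.npat;
  const int ntaxa = ntip + 1;
  std::vector<int> taxon_of_tip(ntip);
  for (int i = 0; i < ntip; ++i) taxon_of_tip[i] = i;
  Partials P;
  down_pass(T, pat, taxon_of_tip, kappa, bf.begin(), P);

  // up messages R_u^(v) per edge e=(u,v): likelihood of everything except
  // v's subtree, conditioned on the state at u, transitions directed away
  // from u (valid for reversible models).  Iterate edges in preorder.
  std::vector<std::vector<double>> Rmsg(T.nedge), Rscale(T.nedge);
  double Pm[16];
  std::vector<int> preorder(T.postorder.rbegin(), T.postorder.rend());
  for (int e : preorder) {
    const int u = T.parent[e], v = T.child[e];
    Rmsg[e].assign((size_t)np * 4, 1.0);
    Rscale[e].assign(np, 0.0);
    // siblings of v at u
    for (int se : T.kids[u]) {
      if (se == e) continue;
      const int w = T.child[se];
      pmatrix(T.elen[se], kappa, bfp, Pm);
      for (int s = 0; s < np; ++s) {
        const double* dw = &P.D[w][(size_t)s * 4];
        double* r = &Rmsg[e][(size_t)s * 4];
        for (int x = 0; x < 4; ++x) {
          double acc = 0.0;
          for (int y = 0; y < 4; ++y) acc += Pm[x * 4 + y] * dw[y];
          r[x] *= acc;
        }
        Rscale[e][s] += P.scale[w][s];
      }
    }
    // contribution from above u
    if (u != T.root) {
      const int pe = T.edge_above[u];
      pmatrix(T.elen[pe], kappa, bfp, Pm);
      for (int s = 0; s < np; ++s) {
        const double* rp = &Rmsg[pe][(size_t)s * 4];
        double* r = &Rmsg[e][(size_t)s * 4];
        double tmp[4];
        for (int x = 0; x < 4; ++x) {
          double acc = 0.0;
          for (int y = 0; y < 4; ++y) acc += Pm[x * 4 + y] * rp[y];
          tmp[x] = acc;
        }
        for (int x = 0; x < 4; ++x) r[x] *= tmp[x];
        Rscale[e][s] += Rscale[pe][s];
      }
    }
    // rescale
    for (int s = 0; s < np; ++s) {
      double* r = &Rmsg[e][(size_t)s * 4];
      double mx = std::max(std::max(r[0], r[1]), std::max(r[2], r[3]));
      if (mx > 0 && mx < 1e-100) {
        for (int x = 0; x < 4; ++x) r[x] /= mx;
        Rscale[e][s] += std::log(mx);
      }
    }
  }

  NumericVector out_lnl(T.nedge), out_pend(T.nedge);
  std::vector<double> G((size_t)np * 4), logscale(np);
  std::vector<int> qcode(np);
  for (int s = 0; s < np; ++s) qcode[s] = pat.codes[(size_t)s * ntaxa + ntip];

  for (int e = 0; e < T.nedge; ++e) {
    const int v = T.child[e];
    const double half = T.elen[e] / 2.0;
    double Pd[16];
    pmatrix(half, kappa, bfp, Pd);
    for (int s = 0; s < np; ++s) {
      const double* dv = &P.D[v][(size_t)s * 4];
      const double* r = &Rmsg[e][(size_t)s * 4];
      double* g = &G[(size_t)s * 4];
      double A[4], B[4];
      for (int x = 0; x < 4; ++x) {
        double accA = 0.0, accB = 0.0;
        for (int y = 0; y < 4; ++y) {
          accA += Pd[x * 4 + y] * dv[y]; // m -> v
          accB += Pd[x * 4 + y] * r[y];  // m -> u (reversible)
        }
        A[x] = accA; B[x] = accB;
      }
      double mx = 0.0;
      for (int x = 0; x < 4; ++x) {
        g[x] = bfp[x] * A[x] * B[x];
        if (g[x] > mx) mx = g[x];
      }
      logscale[s] = P.scale[v][s] + Rscale[e][s];
      if (mx > 0) {
        for (int x = 0; x < 4; ++x) g[x] /= mx;
        logscale[s] += std::log(mx);
      }
    }
    auto lnl_at = [&](double t) {
      double Pq[16];
      pmatrix(t, kappa, bfp, Pq);
      double total = 0.0;
      for (int s = 0; s < np; ++s) {
        const double* g = &G[(size_t)s * 4];
        const int c = qcode[s];
        double L = 0.0;
        if (c < 4) {
          for (int x = 0; x < 4; ++x) L += g[x] * Pq[x * 4 + c];
        } else {
          for (int x = 0; x < 4; ++x) L += g[x];
        }
        total += pat.wts[s] * (std::log(L) + logscale[s]);
      }
      return total;
    };
    double fbest;
    const double tbest = golden_max(lnl_at, pend_lo, pend_hi, tol, &fbest);
    out_lnl[e] = fbest;
    out_pend[e] = tbest;
  }
  return List::create(_["loglik"] = out_lnl, _["pendant"] = out_pend,
                      _["n_patterns"] = np);
}
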