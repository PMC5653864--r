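#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Symmetric k-state Mk model on a rooted time tree.
//
// Transition probabilities have the closed form
//   P(same)  = 1/k + (k-1)/k * exp(-k r t / (k-1))
//   P(other) = 1/k -   1/k   * exp(-k r t / (k-1))
// where r is the total rate of leaving the current state (expected state
// changes per unit time), so no matrix exponentials are needed.  Partial
// likelihoods are rescaled at every node; k <= a few tens is assumed.

namespace {

struct TreeIdx {
  int ntot;                         // tips + internal nodes
  int ntip;
  int root;                         // 0-based index of the root
  std::vector<std::vector<int> > kids;   // child node per node
  std::vector<std::vector<double> > klen; // matching branch lengths
  std::vector<int> postorder;       // node visit order, children first
  std::vector<int> preorder;        // parent before child
};

TreeIdx build_tree(const IntegerMatrix &edge, const NumericVector &elen,
                   int ntip) {
  TreeIdx T;
  int ne = edge.nrow();
  T.ntot = ntip;
  for (int e = 0; e < ne; e++) {
    if (edge(e, 0) > T.ntot) T.ntot = edge(e, 0);
    if (edge(e, 1) > T.ntot) T.ntot = edge(e, 1);
  }
  T.ntip = ntip;
  T.kids.resize(T.ntot);
  T.klen.resize(T.ntot);
  std::vector<bool> is_child(T.ntot, false);
  for (int e = 0; e < ne; e++) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    T.kids[p].push_back(c);
    T.klen[p].push_back(elen[e]);
    is_child[c] = true;
  }
  T.root = ntip; // ape convention; verified below
  for (int i = ntip; i < T.ntot; i++) if (!is_child[i]) { T.root = i; break; }
  // iterative DFS for pre/postorder
  std::vector<int> stack;
  stack.push_back(T.root);
  while (!stack.empty()) {
    int n = stack.back(); stack.pop_back();
    T.preorder.push_back(n);
    for (size_t j = 0; j < T.kids[n].size(); j++) stack.push_back(T.kids[n][j]);
  }
  T.postorder.assign(T.preorder.rbegin(), T.preorder.rend());
  return T;
}

inline void pvec(double r, double t, int k, double &psame, double &pdiff) {
  double e = std::exp(-(double)k * r * t / (double)(k - 1));
  psame = (1.0 + (k - 1) * e) / k;
  pdiff = (1.0 - e) / k;
}

// down-pass partial likelihoods; returns log-likelihood under a flat root
// prior; L is filled (rescaled per node, scale absorbed in return value
// and logscale[] if keep_scale)
double mk_loglik(const TreeIdx &T, const std::vector<int> &tipstate, int k,
                 double r, std::vector<double> &L,
                 std::vector<double> *logscale = 0) {
  double ls_total = 0.0;
  if (logscale) logscale->assign(T.ntot, 0.0);
  for (size_t ii = 0; ii < T.postorder.size(); ii++) {
    int n = T.postorder[ii];
    double *Ln = &L[(size_t)n * k];
    if (n < T.ntip) {
      int s = tipstate[n];
      for (int i = 0; i < k; i++) Ln[i] = (s < 0 || s == i) ? 1.0 : 0.0;
      continue;
    }
    for (int i = 0; i < k; i++) Ln[i] = 1.0;
    for (size_t j = 0; j < T.kids[n].size(); j++) {
      int c = T.kids[n][j];
      double psame, pdiff;
      pvec(r, T.klen[n][j], k, psame, pdiff);
      double *Lc = &L[(size_t)c * k];
      double S = 0.0;
      for (int i = 0; i < k; i++) S += Lc[i];
      for (int i = 0; i < k; i++) Ln[i] *= pdiff * S + (psame - pdiff) * Lc[i];
    }
    double mx = 0.0;
    for (int i = 0; i < k; i++) if (Ln[i] > mx) mx = Ln[i];
    if (mx <= 0.0) return R_NegInf;
    for (int i = 0; i < k; i++) Ln[i] /= mx;
    ls_total += std::log(mx);
    if (logscale) (*logscale)[n] = std::log(mx);
  }
  double tot = 0.0;
  const double *Lr = &L[(size_t)T.root * k];
  for (int i = 0; i < k; i++) tot += Lr[i];
  return std::log(tot / k) + ls_total;
}

// maximisation of the log-likelihood over log(rate): coarse grid scan
// (the Mk profile can plateau at high rates) followed by golden-section
// refinement in the best grid cell
double mk_fit_rate(const TreeIdx &T, const std::vector<int> &tipstate, int k,
                   double lo, double hi, double &best_ll) {
  std::vector<double> L((size_t)T.ntot * k);
  const double gr = 0.381966011250105; // 2 - golden ratio
  const int ngrid = 61;
  double glo = std::log(lo), ghi = std::log(hi);
  double step = (ghi - glo) / (ngrid - 1);
  int ibest = 0;
  double fbest = R_NegInf;
  for (int i = 0; i < ngrid; i++) {
    double f = mk_loglik(T, tipstate, k, std::exp(glo + i * step), L);
    if (f > fbest) { fbest = f; ibest = i; }
  }
  double a = glo + std::max(0, ibest - 1) * step;
  double b = glo + std::min(ngrid - 1, ibest + 1) * step;
  double x1 = a + gr * (b - a), x2 = b - gr * (b - a);
  double f1 = mk_loglik(T, tipstate, k, std::exp(x1), L);
  double f2 = mk_loglik(T, tipstate, k, std::exp(x2), L);
  for (int it = 0; it < 80 && (b - a) > 1e-10; it++) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = b - gr * (b - a);
      f2 = mk_loglik(T, tipstate, k, std::exp(x2), L);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = a + gr * (b - a);
      f1 = mk_loglik(T, tipstate, k, std::exp(x1), L);
    }
  }
  double xm = (a + b) / 2.0;
  best_ll = mk_loglik(T, tipstate, k, std::exp(xm), L);
  return std::exp(xm);
}

// marginal reconstruction: up-pass partials U (information outside the
// subtree, expressed as a distribution over the node's own state), then
// marginal(node) ~ L(node) * U(node)
void mk_marginals(const TreeIdx &T, const std::vector<int> &tipstate, int k,
                  double r, NumericMatrix &marg) {
  std::vector<double> L((size_t)T.ntot * k), U((size_t)T.ntot * k);
  mk_loglik(T, tipstate, k, r, L);
  for (int i = 0; i < k; i++) U[(size_t)T.root * k + i] = 1.0 / k;
  std::vector<double> M(k), PL(k);
  for (size_t ii = 0; ii < T.preorder.size(); ii++) {
    int n = T.preorder[ii];
    for (size_t j = 0; j < T.kids[n].size(); j++) {
      int c = T.kids[n][j];
      // M = U[n] * prod over siblings of (P L_sib)
      for (int i = 0; i < k; i++) M[i] = U[(size_t)n * k + i];
      for (size_t j2 = 0; j2 < T.kids[n].size(); j2++) {
        if (j2 == j) continue;
        int s = T.kids[n][j2];
        double psame, pdiff;
        pvec(r, T.klen[n][j2], k, psame, pdiff);
        double *Ls = &L[(size_t)s * k];
        double S = 0.0;
        for (int i = 0; i < k; i++) S += Ls[i];
        for (int i = 0; i < k; i++) M[i] *= pdiff * S + (psame - pdiff) * Ls[i];
      }
      double psame, pdiff;
      pvec(r, T.klen[n][j], k, psame, pdiff);
      double SM = 0.0;
      for (int i = 0; i < k; i++) SM += M[i];
      double tot = 0.0;
      for (int i = 0; i < k; i++) {
        PL[i] = pdiff * SM + (psame - pdiff) * M[i];
        tot += PL[i];
      }
      if (tot <= 0.0) tot = 1.0;
      for (int i = 0; i < k; i++) U[(size_t)c * k + i] = PL[i] / tot;
    }
  }
  for (int n = 0; n < T.ntot; n++) {
    double tot = 0.0;
    for (int i = 0; i < k; i++) {
      double m = L[(size_t)n * k + i] * U[(size_t)n * k + i];
      marg(n, i) = m;
      tot += m;
    }
    if (tot > 0.0) for (int i = 0; i < k; i++) marg(n, i) /= tot;
  }
}

} // namespace

// [[Rcpp::export(name = ".mk_asr_cpp")]]
List mk_asr_cpp(IntegerMatrix edge, NumericVector elen, int ntip,
                IntegerMatrix tip_states, IntegerVector kvec,
                NumericVector fixed_rate, double rate_lo, double rate_hi,
                bool want_marginals) {
  TreeIdx T = build_tree(edge, elen, ntip);
  int nchar = tip_states.ncol();
  NumericVector rates(nchar), logliks(nchar);
  IntegerMatrix map(T.ntot, nchar);
  List marglist(want_marginals ? nchar : 0);
  std::vector<int> tipstate(ntip);
  for (int c = 0; c < nchar; c++) {
    int k = kvec[c];
    for (int i = 0; i < ntip; i++) tipstate[i] = tip_states(i, c);
    double r, ll;
    if (fixed_rate.size() == nchar && R_finite(fixed_rate[c])) {
      r = fixed_rate[c];
      std::vector<double> L((size_t)T.ntot * k);
      ll = mk_loglik(T, tipstate, k, r, L);
    } else {
      r = mk_fit_rate(T, tipstate, k, rate_lo, rate_hi, ll);
    }
    rates[c] = r;
    logliks[c] = ll;
    NumericMatrix marg(T.ntot, k);
    mk_marginals(T, tipstate, k, r, marg);
    for (int n = 0; n < T.ntot; n++) {
      if (n < ntip) {
        map(n, c) = tipstate[n] >= 0 ? tipstate[n] : NA_INTEGER;
        continue;
      }
      int best = 0;
      for (int i = 1; i < k; i++) if (marg(n, i) > marg(n, best)) best = i;
      map(n, c) = best;
    }
    if (want_marginals) marglist[c] = marg;
  }
  List out = List::create(_["rate"] = rates, _["loglik"] = logliks,
                          _["map"] = map);
  if (want_marginals) out["marginals"] = marglist;
  return out;
}
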