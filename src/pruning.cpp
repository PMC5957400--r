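#include <Rcpp.h>
using namespace Rcpp;

// Likelihood engine for symmetric k-state substitution models (JC for
// nucleotides, Poisson for amino acids).  Transition probabilities have the
// closed form
//   P_same(t) = 1/k + (k-1)/k * e,   P_diff(t) = 1/k * (1 - e),
//   e = exp(-k * t / (k - 1)),
// with t in expected substitutions per site (mean rate 1), so the action of
// P(t) on a partial-likelihood vector L is
//   (P L)_x = P_diff * S + e * L_x,   S = sum_y L_y.
//
// Trees arrive as ape postorder edge matrices (1-based node ids, tips
// 1..nTip, root nTip+1).  Tip states are rows of the phyDat contrast matrix,
// so gaps/ambiguities are handled as partial likelihoods of ones.

static inline void transform_branch(const double *Lin, double *Lout,
                                    const double t, const int k,
                                    const int npat) {
  double tt = t < 0 ? 0 : t;
  const double e = std::exp(-(double)k * tt / (k - 1.0));
  const double pd = (1.0 - e) / k;
  for (int s = 0; s < npat; s++) {
    const double *a = Lin + (size_t)s * k;
    double *b = Lout + (size_t)s * k;
    double S = 0.0;
    for (int x = 0; x < k; x++) S += a[x];
    const double base = pd * S;
    for (int x = 0; x < k; x++) b[x] = base + e * a[x];
  }
}

// Fill lower (post-order) partials for all nodes.  lowers is k x npat x
// nNode; lls is npat x nNode per-pattern log scale factors.  Tip lowers are
// raw contrast rows (no branch applied).
static void fill_lowers(const IntegerMatrix &edge, const NumericVector &el,
                        const int nTip, const int nNode, const List &tip_idx,
                        const NumericMatrix &contrast, const int k,
                        const int npat, std::vector<double> &lowers,
                        std::vector<double> &lls) {
  const size_t nodesz = (size_t)k * npat;
  std::vector<bool> started(nNode, false);
  // tips: expand contrast rows
  for (int i = 0; i < nTip; i++) {
    IntegerVector idx = tip_idx[i];
    double *L = &lowers[(size_t)i * nodesz];
    for (int s = 0; s < npat; s++) {
      int row = idx[s] - 1;
      for (int x = 0; x < k; x++) L[(size_t)s * k + x] = contrast(row, x);
    }
    started[i] = true;
  }
  std::vector<double> tmp(nodesz);
  const int nedge = edge.nrow();
  for (int e = 0; e < nedge; e++) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    transform_branch(&lowers[(size_t)c * nodesz], tmp.data(), el[e], k, npat);
    double *P = &lowers[(size_t)p * nodesz];
    double *lsP = &lls[(size_t)p * npat];
    const double *lsC = &lls[(size_t)c * npat];
    if (!started[p]) {
      std::copy(tmp.begin(), tmp.end(), P);
      for (int s = 0; s < npat; s++) lsP[s] = (c < nTip) ? 0.0 : lsC[s];
      started[p] = true;
    } else {
      for (int s = 0; s < npat; s++) {
        double m = 0.0;
        double *Ps = P + (size_t)s * k;
        const double *ts = tmp.data() + (size_t)s * k;
        for (int x = 0; x < k; x++) {
          Ps[x] *= ts[x];
          if (Ps[x] > m) m = Ps[x];
        }
        if (c >= nTip) lsP[s] += lsC[s];
        if (m > 0 && m < 1e-80) { // rescale to dodge underflow
          for (int x = 0; x < k; x++) Ps[x] /= m;
          lsP[s] += std::log(m);
        }
      }
    }
  }
}

// [[Rcpp::export]]
double plik_full(IntegerMatrix edge, NumericVector el, int nTip, int nNode,
                 List tip_idx, NumericMatrix contrast, NumericVector weight,
                 int k) {
  const int npat = weight.size();
  const size_t nodesz = (size_t)k * npat;
  std::vector<double> lowers(nodesz * nNode, 0.0);
  std::vector<double> lls((size_t)npat * nNode, 0.0);
  fill_lowers(edge, el, nTip, nNode, tip_idx, contrast, k, npat, lowers, lls);
  const int root = nTip; // 0-based id of root (ape: nTip + 1)
  const double *R = &lowers[(size_t)root * nodesz];
  const double *ls = &lls[(size_t)root * npat];
  double lnL = 0.0;
  for (int s = 0; s < npat; s++) {
    double tot = 0.0;
    for (int x = 0; x < k; x++) tot += R[(size_t)s * k + x];
    lnL += weight[s] * (std::log(tot / k) + ls[s]);
  }
  return lnL;
}

// Lower partials for every node plus upper partials for every edge.  The
// upper of edge e=(p,c) collects the whole tree except the subtree below c,
// viewed from p, so the tree log-likelihood as a function of e's length is
//   sum_s w_s [ log( (1/k) sum_x U_x (P(t) L_c)_x ) + uls_s + lls_c,s ].
// [[Rcpp::export]]
List plik_cache(IntegerMatrix edge, NumericVector el, int nTip, int nNode,
                List tip_idx, NumericMatrix contrast, NumericVector weight,
                int k) {
  const int npat = weight.size();
  const int nedge = edge.nrow();
  const size_t nodesz = (size_t)k * npat;
  NumericVector lowers(nodesz * nNode);
  NumericVector lls((size_t)npat * nNode);
  std::vector<double> lo(nodesz * nNode, 0.0), lsc((size_t)npat * nNode, 0.0);
  fill_lowers(edge, el, nTip, nNode, tip_idx, contrast, k, npat, lo, lsc);
  std::copy(lo.begin(), lo.end(), lowers.begin());
  std::copy(lsc.begin(), lsc.end(), lls.begin());

  NumericVector uppers(nodesz * nedge);
  NumericVector uls((size_t)npat * nedge);
  // edge index whose child is node v (parent edge), -1 for root
  std::vector<int> pedge(nNode, -1);
  for (int e = 0; e < nedge; e++) pedge[edge(e, 1) - 1] = e;
  std::vector<double> tmp(nodesz);
  // reverse postorder = preorder over edges
  for (int e = nedge - 1; e >= 0; e--) {
    const int p = edge(e, 0) - 1;
    double *U = &uppers[(size_t)e * nodesz];
    double *Us = &uls[(size_t)e * npat];
    for (size_t i = 0; i < nodesz; i++) U[i] = 1.0;
    for (int s = 0; s < npat; s++) Us[s] = 0.0;
    // contribution from above (parent edge of p), absent at the root
    const int pe = pedge[p];
    if (pe >= 0) {
      transform_branch(&uppers[(size_t)pe * nodesz], tmp.data(), el[pe], k,
                       npat);
      for (size_t i = 0; i < nodesz; i++) U[i] *= tmp[i];
      for (int s = 0; s < npat; s++) Us[s] += uls[(size_t)pe * npat + s];
    }
    // contributions from siblings (other children of p)
    for (int f = 0; f < nedge; f++) {
      if (f == e || edge(f, 0) - 1 != p) continue;
      const int sib = edge(f, 1) - 1;
      transform_branch(&lo[(size_t)sib * nodesz], tmp.data(), el[f], k, npat);
      for (int s = 0; s < npat; s++) {
        double m = 0.0;
        for (int x = 0; x < k; x++) {
          U[(size_t)s * k + x] *= tmp[(size_t)s * k + x];
          if (U[(size_t)s * k + x] > m) m = U[(size_t)s * k + x];
        }
        if (sib >= nTip) Us[s] += lsc[(size_t)sib * npat + s];
        if (m > 0 && m < 1e-80) {
          for (int x = 0; x < k; x++) U[(size_t)s * k + x] /= m;
          Us[s] += std::log(m);
        }
      }
    }
  }
  return List::create(_["lowers"] = lowers, _["lls"] = lls,
                      _["uppers"] = uppers, _["uls"] = uls);
}

// Log-likelihood and its gradient with respect to every edge length, from
// one lower+upper pass.  For the symmetric model,
//   d(P(t)L)_x/dt = e * k/(k-1) * (S/k - L_x),  e = exp(-kt/(k-1)),
// and per-pattern scale factors cancel in the ratio d(siteL)/siteL.
// Per-edge transformed contributions tc[e] = P(el_e) lower(child_e) are
// stored during the lower pass and reused for sibling products, keeping
// the upper pass linear in the number of edges.
// [[Rcpp::export]]
List plik_grad(IntegerMatrix edge, NumericVector el, int nTip, int nNode,
               List tip_idx, NumericMatrix contrast, NumericVector weight,
               int k) {
  const int npat = weight.size();
  const int nedge = edge.nrow();
  const size_t nodesz = (size_t)k * npat;
  // lower pass with stored per-edge transformed contributions
  std::vector<double> lo(nodesz * nNode, 0.0), lsc((size_t)npat * nNode, 0.0);
  std::vector<double> tc(nodesz * nedge);
  std::vector<bool> started(nNode, false);
  for (int i = 0; i < nTip; i++) {
    IntegerVector idx = tip_idx[i];
    double *L = &lo[(size_t)i * nodesz];
    for (int s = 0; s < npat; s++) {
      int row = idx[s] - 1;
      for (int x = 0; x < k; x++) L[(size_t)s * k + x] = contrast(row, x);
    }
  }
  for (int e = 0; e < nedge; e++) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    double *T = &tc[(size_t)e * nodesz];
    transform_branch(&lo[(size_t)c * nodesz], T, el[e], k, npat);
    double *P = &lo[(size_t)p * nodesz];
    double *lsP = &lsc[(size_t)p * npat];
    const double *lsC = &lsc[(size_t)c * npat];
    if (!started[p]) {
      std::copy(T, T + nodesz, P);
      for (int s = 0; s < npat; s++) lsP[s] = (c < nTip) ? 0.0 : lsC[s];
      started[p] = true;
    } else {
      for (int s = 0; s < npat; s++) {
        double m = 0.0;
        double *Ps = P + (size_t)s * k;
        const double *ts = T + (size_t)s * k;
        for (int x = 0; x < k; x++) {
          Ps[x] *= ts[x];
          if (Ps[x] > m) m = Ps[x];
        }
        if (c >= nTip) lsP[s] += lsC[s];
        if (m > 0 && m < 1e-80) {
          for (int x = 0; x < k; x++) Ps[x] /= m;
          lsP[s] += std::log(m);
        }
      }
    }
  }
  // upper pass: upper[e] = P(el_pe) upper[pe] (x) prod_{siblings f} tc[f]
  std::vector<double> up(nodesz * nedge, 1.0);
  std::vector<int> pedge(nNode, -1);
  for (int e = 0; e < nedge; e++) pedge[edge(e, 1) - 1] = e;
  std::vector<double> tmp(nodesz);
  for (int e = nedge - 1; e >= 0; e--) {
    const int p = edge(e, 0) - 1;
    double *U = &up[(size_t)e * nodesz];
    const int pe = pedge[p];
    if (pe >= 0) {
      transform_branch(&up[(size_t)pe * nodesz], tmp.data(), el[pe], k, npat);
      std::copy(tmp.begin(), tmp.end(), U);
    }
    for (int f = 0; f < nedge; f++) {
      if (f == e || edge(f, 0) - 1 != p) continue;
      const double *T = &tc[(size_t)f * nodesz];
      for (size_t i = 0; i < nodesz; i++) U[i] *= T[i];
    }
    // per-pattern rescale (relative magnitude only; scales cancel below)
    for (int s = 0; s < npat; s++) {
      double m = 0.0;
      double *Us = U + (size_t)s * k;
      for (int x = 0; x < k; x++) if (Us[x] > m) m = Us[x];
      if (m > 0 && m < 1e-80)
        for (int x = 0; x < k; x++) Us[x] /= m;
    }
  }
  // lnL from the root lowers (scales tracked exactly there)
  const int root = nTip;
  double lnL = 0.0;
  for (int s = 0; s < npat; s++) {
    double tot = 0.0;
    for (int x = 0; x < k; x++) tot += lo[(size_t)root * nodesz + s * k + x];
    lnL += weight[s] * (std::log(tot / k) + lsc[(size_t)root * npat + s]);
  }
  // gradient per edge: scale factors cancel in the ratio
  NumericVector grad(nedge);
  const double a = (double)k / (k - 1.0);
  for (int e = 0; e < nedge; e++) {
    const int c = edge(e, 1) - 1;
    double tt = el[e] < 0 ? 0 : el[e];
    const double ex = std::exp(-a * tt);
    const double pd = (1.0 - ex) / k;
    const double *L = &lo[(size_t)c * nodesz];
    const double *U = &up[(size_t)e * nodesz];
    double g = 0.0;
    for (int s = 0; s < npat; s++) {
      double S = 0.0, num = 0.0, den = 0.0;
      const double *Ls = L + (size_t)s * k;
      const double *Us = U + (size_t)s * k;
      for (int x = 0; x < k; x++) S += Ls[x];
      const double base = pd * S;
      for (int x = 0; x < k; x++) {
        den += Us[x] * (base + ex * Ls[x]);
        num += Us[x] * (ex * a * (S / k - Ls[x]));
      }
      if (den > 0) g += weight[s] * num / den;
    }
    grad[e] = g;
  }
  return List::create(_["lnl"] = lnL, _["grad"] = grad);
}

// Log-likelihood as a function of one edge length, using cached partials.
// e_idx is the 0-based row of the postorder edge matrix.
// [[Rcpp::export]]
double plik_edge(double t, int e_idx, IntegerMatrix edge, int nTip,
                 NumericVector lowers, NumericVector lls,
                 NumericVector uppers, NumericVector uls, NumericVector weight,
                 int k) {
  const int npat = weight.size();
  const size_t nodesz = (size_t)k * npat;
  const int c = edge(e_idx, 1) - 1;
  const double *L = &lowers[(size_t)c * nodesz];
  const double *U = &uppers[(size_t)e_idx * nodesz];
  const double *Us = &uls[(size_t)e_idx * npat];
  const double *Ls = &lls[(size_t)c * npat];
  double tt = t < 0 ? 0 : t;
  const double e = std::exp(-(double)k * tt / (k - 1.0));
  const double pd = (1.0 - e) / k;
  double lnL = 0.0;
  for (int s = 0; s < npat; s++) {
    const double *a = L + (size_t)s * k;
    const double *u = U + (size_t)s * k;
    double S = 0.0;
    for (int x = 0; x < k; x++) S += a[x];
    const double base = pd * S;
    double tot = 0.0;
    for (int x = 0; x < k; x++) tot += u[x] * (base + e * a[x]);
    double extra = (c < nTip) ? Us[s] : Us[s] + Ls[s];
    lnL += weight[s] * (std::log(tot / k) + extra);
  }
  return lnL;
}
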