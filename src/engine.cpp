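// Codon site-class mixture log-likelihood via Felsenstein pruning.
//
// The tree arrives as an ape edge matrix in postorder; tips are nodes
// 1..ntaxa, the root is ntaxa+1 (binary or basal multifurcation). Site
// patterns are pre-compressed in R and carry multiplicity weights. Each
// site class assigns one omega per branch partition (background/reference
// = 0, foreground/test = 1); rate matrices are Goldman-Yang style
// (single-nucleotide steps, kappa on transitions, omega on nonsynonymous
// changes, target-codon frequency), jointly rescaled by the expected rate
// of the background mixture so branch lengths are expected substitutions
// per codon under the background process.
//
// Two structural optimizations keep desk-scale replicate batteries cheap:
// subtree partials are memoized across site classes (classes that share
// omegas over a whole subtree share its partials - the big win for the
// branch-site model, where classes differ only on the foreground edge),
// and for tip edges only the needed columns of P(t) are formed, since a
// tip's partial is an indicator vector.

#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <sstream>

using namespace arma;

namespace {

struct Engine {
  mat stepTi, stepTv, nsMask;
  vec pi, sqp, isq;
  std::vector<vec> eval;
  std::vector<mat> evec;
  std::vector<double> rate;

  void buildOmega(double kappa, const std::vector<double>& omegas) {
    int M = omegas.size();
    eval.resize(M); evec.resize(M); rate.resize(M);
    for (int m = 0; m < M; ++m) {
      mat Q = (stepTi * kappa + stepTv);
      Q = Q % ((1.0 - nsMask) + nsMask * omegas[m]);
      Q.each_row() %= pi.t();
      Q.diag() -= sum(Q, 1);
      rate[m] = -dot(pi, Q.diag());
      mat A = Q;
      A.each_col() %= sqp;
      A.each_row() %= isq.t();
      A = 0.5 * (A + A.t());
      vec ev; mat U;
      eig_sym(ev, U, A);
      eval[m] = ev; evec[m] = U;
    }
  }

  // full transition matrix
  mat pmat(int m, double t) const {
    vec e = exp(eval[m] * t);
    mat V = evec[m];
    V.each_row() %= sqrt(e).t();
    mat P = V * V.t();
    P.each_col() %= isq;
    P.each_row() %= sqp.t();
    P.elem(find(P < 0)).zeros();
    return P;
  }

  // only the columns `cols` (0-based) of P(t)
  mat pcols(int m, double t, const uvec& cols) const {
    vec e = exp(eval[m] * t);
    mat R = evec[m].rows(cols).t();   // 61 x |S|
    R.each_col() %= e;
    mat P = evec[m] * R;
    P.each_col() %= isq;
    P.each_row() %= sqp.elem(cols).t();
    P.elem(find(P < 0)).zeros();
    return P;
  }
};

} // namespace

// [[Rcpp::export(name = ".pd_mixture_loglik")]]
Rcpp::List pd_mixture_loglik(
    const arma::imat& tips,        // ntaxa x npat, 1-based, 0 = missing
    const arma::vec& weights,
    const arma::imat& edge,        // nedge x 2 postorder, 1-based
    const arma::vec& edgeLen,
    const arma::ivec& edgePart,    // 0 background, 1 foreground
    double kappa,
    const arma::vec& pi,
    const arma::mat& classOmega,   // nclass x 2
    const arma::vec& classProp,
    const arma::mat& stepM, const arma::mat& tiM, const arma::mat& nsM,
    bool wantSitePosteriors) {

  const int ntaxa = tips.n_rows, npat = tips.n_cols;
  const int nedge = edge.n_rows, nclass = classOmega.n_rows;
  const int nnode = nedge + 1;
  const int nstate = pi.n_elem;

  Engine eng;
  eng.stepTi = stepM % tiM;
  eng.stepTv = stepM % (1.0 - tiM);
  eng.nsMask = nsM;
  eng.pi = pi;
  eng.sqp = sqrt(pi);
  eng.isq = 1.0 / eng.sqp;

  // distinct omegas across (class, partition)
  std::vector<double> omegas;
  imat classIdx(nclass, 2);
  for (int c = 0; c < nclass; ++c)
    for (int p = 0; p < 2; ++p) {
      double w = classOmega(c, p);
      int found = -1;
      for (size_t m = 0; m < omegas.size(); ++m)
        if (omegas[m] == w) { found = (int)m; break; }
      if (found < 0) { omegas.push_back(w); found = omegas.size() - 1; }
      classIdx(c, p) = found;
    }
  eng.buildOmega(kappa, omegas);

  // common scale: expected rate of the background mixture
  double f = 0.0;
  for (int c = 0; c < nclass; ++c) f += classProp(c) * eng.rate[classIdx(c, 0)];
  if (f < 1e-300) f = 1.0;

  // per tip: distinct observed states and per-pattern index into them
  std::vector<uvec> tipStates(ntaxa);
  std::vector<ivec> tipMap(ntaxa);      // -1 = missing
  for (int i = 0; i < ntaxa; ++i) {
    std::map<int,int> seen;
    ivec mp(npat);
    std::vector<arma::uword> st;
    for (int j = 0; j < npat; ++j) {
      int s = tips(i, j);
      if (s <= 0) { mp(j) = -1; continue; }
      auto it = seen.find(s);
      if (it == seen.end()) {
        seen.emplace(s, (int)st.size());
        st.push_back((arma::uword)(s - 1));
        mp(j) = st.size() - 1;
      } else mp(j) = it->second;
    }
    tipStates[i] = uvec(st);
    tipMap[i] = mp;
  }

  // caches: full P for internal edges, P columns for tip edges
  std::map<long long, mat> pcache, pccache;
  auto getP = [&](int m, int e) -> const mat& {
    long long key = (long long)m * nedge + e;
    auto it = pcache.find(key);
    if (it == pcache.end())
      it = pcache.emplace(key, eng.pmat(m, edgeLen(e) / f)).first;
    return it->second;
  };
  auto getPcols = [&](int m, int e, int tip) -> const mat& {
    long long key = (long long)m * nedge + e;
    auto it = pccache.find(key);
    if (it == pccache.end())
      it = pccache.emplace(key,
        eng.pcols(m, edgeLen(e) / f, tipStates[tip])).first;
    return it->second;
  };

  std::vector<std::vector<int>> childEdges(nnode);
  for (int e = 0; e < nedge; ++e) childEdges[edge(e, 0) - 1].push_back(e);
  const int root = ntaxa;

  // memoized subtree partials across classes
  std::vector<std::string> sigOf(nnode);
  std::map<std::string, int> memoIndex;
  std::vector<mat> memoPartial;
  std::vector<rowvec> memoScale;

  mat patClassLog(npat, nclass);

  // internal nodes in completion order (last child edge in postorder)
  std::vector<int> lastEdge(nnode, -1);
  for (int e = 0; e < nedge; ++e) lastEdge[edge(e, 0) - 1] = e;
  std::vector<std::pair<int,int>> nodeOrder;
  for (int n = ntaxa; n < nnode; ++n)
    if (!childEdges[n].empty()) nodeOrder.push_back({lastEdge[n], n});
  std::sort(nodeOrder.begin(), nodeOrder.end());

  for (int c = 0; c < nclass; ++c) {
    for (int n = 0; n < nnode; ++n) sigOf[n].clear();
    for (int n = 0; n < ntaxa; ++n) sigOf[n] = "T";

    for (auto& pr : nodeOrder) {
      int n = pr.second;
      std::ostringstream key;
      key << "N" << n;
      for (int e : childEdges[n]) {
        int ch = edge(e, 1) - 1;
        int m = classIdx(c, edgePart(e));
        key << "|" << m << ":" << sigOf[ch];
      }
      std::string sig = key.str();
      sigOf[n] = sig;
      if (memoIndex.count(sig)) continue;

      mat part(nstate, npat, fill::ones);
      rowvec scal(npat, fill::zeros);
      for (int e : childEdges[n]) {
        int ch = edge(e, 1) - 1;
        int m = classIdx(c, edgePart(e));
        if (ch < ntaxa) {
          const mat& PC = getPcols(m, e, ch);
          const ivec& mp = tipMap[ch];
          for (int j = 0; j < npat; ++j)
            if (mp(j) >= 0) part.col(j) %= PC.col(mp(j));
        } else {
          const mat& P = getP(m, e);
          int mi = memoIndex[sigOf[ch]];
          part %= (P * memoPartial[mi]);
          scal += memoScale[mi];
        }
      }
      rowvec mx = max(part, 0);
      mx.elem(find(mx <= 0)).ones();
      part.each_row() /= mx;
      scal += log(mx);
      memoIndex[sig] = memoPartial.size();
      memoPartial.push_back(std::move(part));
      memoScale.push_back(std::move(scal));
    }

    int ri = memoIndex[sigOf[root]];
    rowvec lik = eng.pi.t() * memoPartial[ri];
    patClassLog.col(c) = (log(lik) + memoScale[ri]).t();
  }

  vec sitelog(npat);
  vec lp = log(classProp);
  lp.elem(find_nonfinite(lp)).fill(-1e300);
  for (int j = 0; j < npat; ++j) {
    double mxv = -datum::inf;
    for (int c = 0; c < nclass; ++c)
      mxv = std::max(mxv, patClassLog(j, c) + lp(c));
    double s = 0;
    for (int c = 0; c < nclass; ++c)
      s += std::exp(patClassLog(j, c) + lp(c) - mxv);
    sitelog(j) = mxv + std::log(s);
  }
  double ll = dot(weights, sitelog);

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("logLik") = ll,
    Rcpp::Named("scaleFactor") = f);
  if (wantSitePosteriors)
    out["patClassLog"] = patClassLog;
  return out;
}
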