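#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Collapsed Gibbs sampler for a Dirichlet-process mixture of independent
// per-sample binomials: mutation m in cluster c has
//   alt[m,s] ~ Binomial(depth[m,s], theta[c,s]),  theta[c,s] ~ Beta(a,b).
// theta is integrated out, so each cluster keeps only the running sums of
// alt and depth per sample.  Cluster labels are kept compact (an emptied
// cluster is replaced by the last one).  Uses R's RNG.

static inline double marg_term(double a, double b, double A, double D,
                               double x, double n) {
  // log predictive of (x, n) given cluster sums (A, D): beta-binomial kernel
  return R::lbeta(a + A + x, b + (D - A) + (n - x)) -
         R::lbeta(a + A, b + D - A);
}

// [[Rcpp::export]]
List dp_gibbs_cpp(const IntegerMatrix alt, const IntegerMatrix depth,
                  double alpha, double a, double b, int burnin, int nsamples,
                  int thin) {
  const int M = alt.nrow(), S = alt.ncol();
  const int niter = burnin + nsamples;

  // log marginal likelihood of a mutation in a brand-new cluster
  std::vector<double> lml_new(M);
  const double lbeta_ab = R::lbeta(a, b);
  for (int m = 0; m < M; ++m) {
    double v = 0.0;
    for (int s = 0; s < S; ++s)
      v += R::lbeta(a + alt(m, s), b + depth(m, s) - alt(m, s)) - lbeta_ab;
    lml_new[m] = v;
  }

  // state: all mutations start in one cluster
  std::vector<int> z(M, 0);
  std::vector<std::vector<double> > A(1, std::vector<double>(S, 0.0));
  std::vector<std::vector<double> > D(1, std::vector<double>(S, 0.0));
  std::vector<int> nc(1, M);
  for (int m = 0; m < M; ++m)
    for (int s = 0; s < S; ++s) {
      A[0][s] += alt(m, s);
      D[0][s] += depth(m, s);
    }

  NumericMatrix psm(M, M);
  IntegerVector ktrace(niter);
  std::vector<int> best_z(z);
  double best_score = R_NegInf;
  int kept = 0;
  const double lalpha = std::log(alpha);
  std::vector<double> logp;
  std::vector<std::vector<int> > members;

  for (int it = 0; it < niter; ++it) {
    for (int m = 0; m < M; ++m) {
      int k = z[m];
      nc[k]--;
      for (int s = 0; s < S; ++s) {
        A[k][s] -= alt(m, s);
        D[k][s] -= depth(m, s);
      }
      if (nc[k] == 0) {
        const int last = (int)nc.size() - 1;
        if (k != last) {
          nc[k] = nc[last];
          A[k].swap(A[last]);
          D[k].swap(D[last]);
          for (int mm = 0; mm < M; ++mm)
            if (z[mm] == last) z[mm] = k;
        }
        nc.pop_back();
        A.pop_back();
        D.pop_back();
      }
      const int K = (int)nc.size();
      logp.resize(K + 1);
      double mx = R_NegInf;
      for (int kk = 0; kk < K; ++kk) {
        double lp = std::log((double)nc[kk]);
        for (int s = 0; s < S; ++s)
          lp += marg_term(a, b, A[kk][s], D[kk][s], alt(m, s), depth(m, s));
        logp[kk] = lp;
        if (lp > mx) mx = lp;
      }
      logp[K] = lalpha + lml_new[m];
      if (logp[K] > mx) mx = logp[K];
      double tot = 0.0;
      for (int kk = 0; kk <= K; ++kk) {
        logp[kk] = std::exp(logp[kk] - mx);
        tot += logp[kk];
      }
      double u = unif_rand() * tot;
      int pick = 0;
      for (; pick < K; ++pick) {
        u -= logp[pick];
        if (u <= 0) break;
      }
      if (pick == K) {
        nc.push_back(0);
        A.push_back(std::vector<double>(S, 0.0));
        D.push_back(std::vector<double>(S, 0.0));
      }
      z[m] = pick;
      nc[pick]++;
      for (int s = 0; s < S; ++s) {
        A[pick][s] += alt(m, s);
        D[pick][s] += depth(m, s);
      }
    }

    const int K = (int)nc.size();
    ktrace[it] = K;

    if (it >= burnin && ((it - burnin) % thin == 0)) {
      kept++;
      members.assign(K, std::vector<int>());
      for (int m = 0; m < M; ++m) members[z[m]].push_back(m);
      for (int kk = 0; kk < K; ++kk) {
        const std::vector<int> &mem = members[kk];
        const int n = (int)mem.size();
        for (int u1 = 0; u1 < n; ++u1)
          for (int u2 = u1; u2 < n; ++u2) {
            psm(mem[u1], mem[u2]) += 1.0;
            if (u1 != u2) psm(mem[u2], mem[u1]) += 1.0;
          }
      }
      // joint score: DP partition prior (EPPF) x marginal likelihood
      double score = K * lalpha;
      for (int kk = 0; kk < K; ++kk) {
        score += std::lgamma((double)nc[kk]);
        for (int s = 0; s < S; ++s)
          score += R::lbeta(a + A[kk][s], b + D[kk][s] - A[kk][s]) - lbeta_ab;
      }
      if (score > best_score) {
        best_score = score;
        best_z = z;
      }
    }
  }

  if (kept > 0)
    for (int i = 0; i < M * M; ++i) psm[i] /= kept;

  return List::create(_["psm"] = psm, _["k_trace"] = ktrace,
                      _["map_assign"] = wrap(best_z),
                      _["map_log_score"] = best_score, _["n_kept"] = kept);
}
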