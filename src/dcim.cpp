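// Collapsed Gibbs sampler for the differential co-expression infinite
// mixture model.  Three nested Dirichlet-process allocations are sampled:
//   C : genes   -> global expression-pattern clusters   (concentration alpha)
//   D : samples -> contexts                             (concentration beta)
//   L : (global cluster, context) -> local cluster      (concentration phi)
// Cluster means and variances are integrated out analytically under an
// independent Normal-Inverse-Gamma prior per (local cluster, context, sample)
// dimension, so every full conditional is available in closed form.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double LOG_2PI = 1.8378770664093454836;

// ---------------------------------------------------------------------------
// Normal-Inverse-Gamma closed forms (one data dimension)
// ---------------------------------------------------------------------------

// log marginal likelihood of n iid Gaussian observations with sum s1 and
// sum of squares s2, mean/variance integrated out under
// NIG(m0, lambda, a, tau).  Computed in the numerically stable centered form:
// tau_n = tau + 0.5 * (ss + lambda*n/(lambda+n) * (xbar - m0)^2) >= tau.
static inline double nig_logm(double n, double s1, double s2,
                              double m0, double lambda, double a, double tau) {
  if (n <= 0.0) return 0.0;
  double ln   = lambda + n;
  double xbar = s1 / n;
  double ss   = s2 - n * xbar * xbar;
  if (ss < 0.0) ss = 0.0;  // roundoff guard
  double dev  = xbar - m0;
  double taun = tau + 0.5 * (ss + (lambda * n / ln) * dev * dev);
  double an   = a + 0.5 * n;
  return -0.5 * n * LOG_2PI + 0.5 * std::log(lambda / ln)
         + a * std::log(tau) - an * std::log(taun)
         + std::lgamma(an) - std::lgamma(a);
}

// log posterior-predictive density of x given the same sufficient statistics:
// a Student-t with 2*a_n df.  Equals nig_logm(n+1,...) - nig_logm(n,...).
static inline double nig_logpred(double x, double n, double s1, double s2,
                                 double m0, double lambda, double a,
                                 double tau) {
  double ln = lambda + n;
  double mn, taun, an;
  if (n > 0.0) {
    double xbar = s1 / n;
    double ss   = s2 - n * xbar * xbar;
    if (ss < 0.0) ss = 0.0;
    double dev  = xbar - m0;
    mn   = (lambda * m0 + s1) / ln;
    taun = tau + 0.5 * (ss + (lambda * n / ln) * dev * dev);
    an   = a + 0.5 * n;
  } else {
    mn = m0; taun = tau; an = a;
  }
  double ln1 = ln + 1.0;
  double d   = x - mn;
  double tau1 = taun + 0.5 * (ln / ln1) * d * d;
  return -0.5 * LOG_2PI + 0.5 * std::log(ln / ln1)
         + an * std::log(taun) - (an + 0.5) * std::log(tau1)
         + std::lgamma(an + 0.5) - std::lgamma(an);
}

// [[Rcpp::export(name = ".nig_logm_cpp")]]
double nig_logm_cpp(NumericVector values, double m0, double lambda,
                    double a, double tau) {
  double n = values.size(), s1 = 0.0, s2 = 0.0;
  for (double v : values) { s1 += v; s2 += v * v; }
  return nig_logm(n, s1, s2, m0, lambda, a, tau);
}

// [[Rcpp::export(name = ".nig_logpred_cpp")]]
double nig_logpred_cpp(double x, double n, double s1, double s2,
                       double m0, double lambda, double a, double tau) {
  return nig_logpred(x, n, s1, s2, m0, lambda, a, tau);
}

// ---------------------------------------------------------------------------
// small utilities
// ---------------------------------------------------------------------------

static inline double log_sum_exp(const std::vector<double>& w) {
  double m = R_NegInf;
  for (double v : w) if (v > m) m = v;
  if (!R_FINITE(m)) return m;
  double s = 0.0;
  for (double v : w) s += std::exp(v - m);
  return m + std::log(s);
}

// Gumbel-max categorical draw from unnormalized log weights (single RNG
// stream, no explicit normalization needed).
static inline int gumbel_max(const std::vector<double>& logw) {
  int best = 0;
  double bestv = R_NegInf;
  for (size_t k = 0; k < logw.size(); ++k) {
    double g = logw[k] - std::log(-std::log(unif_rand()));
    if (g > bestv) { bestv = g; best = (int)k; }
  }
  return best;
}

// sequential CRP partition of n items; returns 0-based labels
static std::vector<int> crp_partition(int n, double conc) {
  std::vector<int> lab(n);
  std::vector<int> sz;
  for (int i = 0; i < n; ++i) {
    double tot = i + conc;
    double u = unif_rand() * tot;
    double acc = 0.0;
    int pick = (int)sz.size();
    for (size_t k = 0; k < sz.size(); ++k) {
      acc += sz[k];
      if (u < acc) { pick = (int)k; break; }
    }
    if (pick == (int)sz.size()) sz.push_back(1); else sz[pick]++;
    lab[i] = pick;
  }
  return lab;
}

// ---------------------------------------------------------------------------
// sampler state
// ---------------------------------------------------------------------------

struct State {
  int N, M;
  const NumericMatrix& X;
  // prior
  std::vector<double> m0;          // per-sample prior mean
  double lambda, a, tau;
  double alpha, beta, phi;
  bool prior_only;
  bool fixed_D;
  int aux_m;                       // auxiliary contexts for new-context moves

  // global gene clusters
  std::vector<int> C;                       // gene -> cluster (0-based)
  std::vector<int> csize;                   // Q
  std::vector<std::vector<double> > g1, g2; // Q x M cluster sums

  // contexts
  std::vector<int> D;                       // sample -> context
  std::vector<int> dsize;                   // R

  // local structure, per context r
  std::vector<std::vector<int> > L;         // R x Q  local label of cluster q
  std::vector<std::vector<int> > mloc;      // R x T_r  #global clusters
  std::vector<std::vector<int> > nloc;      // R x T_r  #genes
  std::vector<std::vector<std::vector<double> > > l1, l2; // R x T_r x M

  State(const NumericMatrix& X_) : X(X_) {
    N = X.nrow(); M = X.ncol();
  }

  int Q() const { return (int)csize.size(); }
  int R() const { return (int)dsize.size(); }

  double logpred_dim(double x, double n, double s1, double s2, int j) const {
    return nig_logpred(x, n, s1, s2, m0[j], lambda, a, tau);
  }
  double logm_dim(double n, double s1, double s2, int j) const {
    return nig_logm(n, s1, s2, m0[j], lambda, a, tau);
  }

  // ---- initialization: singleton gene clusters, one context (or fixed D),
  //      identity local clustering ----
  void init(const IntegerVector& fixed_contexts) {
    C.resize(N); csize.assign(N, 1);
    g1.assign(N, std::vector<double>(M));
    g2.assign(N, std::vector<double>(M));
    for (int i = 0; i < N; ++i) {
      C[i] = i;
      for (int j = 0; j < M; ++j) {
        double x = X(i, j);
        g1[i][j] = x; g2[i][j] = x * x;
      }
    }
    D.resize(M);
    if (fixed_contexts.size() == M) {
      int R0 = 0;
      for (int j = 0; j < M; ++j) {
        D[j] = fixed_contexts[j] - 1;            // 1-based from R
        if (D[j] + 1 > R0) R0 = D[j] + 1;
      }
      dsize.assign(R0, 0);
      for (int j = 0; j < M; ++j) dsize[D[j]]++;
    } else {
      std::fill(D.begin(), D.end(), 0);
      dsize.assign(1, M);
    }
    int R0 = R();
    L.assign(R0, std::vector<int>());
    mloc.assign(R0, std::vector<int>());
    nloc.assign(R0, std::vector<int>());
    l1.assign(R0, std::vector<std::vector<double> >());
    l2.assign(R0, std::vector<std::vector<double> >());
    for (int r = 0; r < R0; ++r) identity_local(r);
  }

  // identity local clustering of context r from current global clusters
  void identity_local(int r) {
    int q = Q();
    L[r].resize(q);
    mloc[r].assign(q, 1);
    nloc[r] = csize;
    l1[r] = g1; l2[r] = g2;
    for (int k = 0; k < q; ++k) L[r][k] = k;
  }

  // build a context's local structure from a partition of global clusters
  void local_from_partition(int r, const std::vector<int>& part) {
    int q = Q();
    int T = 0;
    for (int k = 0; k < q; ++k) if (part[k] + 1 > T) T = part[k] + 1;
    L[r] = part;
    mloc[r].assign(T, 0);
    nloc[r].assign(T, 0);
    l1[r].assign(T, std::vector<double>(M, 0.0));
    l2[r].assign(T, std::vector<double>(M, 0.0));
    for (int k = 0; k < q; ++k) {
      int t = part[k];
      mloc[r][t]++; nloc[r][t] += csize[k];
      for (int j = 0; j < M; ++j) {
        l1[r][t][j] += g1[k][j];
        l2[r][t][j] += g2[k][j];
      }
    }
  }

  // ---- gene-level bookkeeping ----
  void delete_local(int r, int t) {
    mloc[r].erase(mloc[r].begin() + t);
    nloc[r].erase(nloc[r].begin() + t);
    l1[r].erase(l1[r].begin() + t);
    l2[r].erase(l2[r].begin() + t);
    for (size_t k = 0; k < L[r].size(); ++k) if (L[r][k] > t) L[r][k]--;
  }

  void delete_cluster(int q) {   // requires csize[q] == 0
    for (int r = 0; r < R(); ++r) {
      int t = L[r][q];
      mloc[r][t]--;
      if (mloc[r][t] == 0) delete_local(r, t);
      L[r].erase(L[r].begin() + q);
    }
    csize.erase(csize.begin() + q);
    g1.erase(g1.begin() + q);
    g2.erase(g2.begin() + q);
    for (int i = 0; i < N; ++i) if (C[i] > q) C[i]--;
  }

  void remove_gene(int i) {
    int q = C[i];
    C[i] = -1;
    csize[q]--;
    for (int j = 0; j < M; ++j) {
      double x = X(i, j), x2 = x * x;
      g1[q][j] -= x; g2[q][j] -= x2;
      for (int r = 0; r < R(); ++r) {
        int t = L[r][q];
        l1[r][t][j] -= x; l2[r][t][j] -= x2;
      }
    }
    for (int r = 0; r < R(); ++r) nloc[r][L[r][q]]--;
    if (csize[q] == 0) delete_cluster(q);
  }

  void add_gene(int i, int q) {
    C[i] = q;
    csize[q]++;
    for (int j = 0; j < M; ++j) {
      double x = X(i, j), x2 = x * x;
      g1[q][j] += x; g2[q][j] += x2;
      for (int r = 0; r < R(); ++r) {
        int t = L[r][q];
        l1[r][t][j] += x; l2[r][t][j] += x2;
      }
    }
    for (int r = 0; r < R(); ++r) nloc[r][L[r][q]]++;
  }

  // attach existing global cluster q to local cluster t of context r
  // (t == T_r means a new local cluster); q must be detached in r
  void attach_local(int r, int q, int t) {
    int T = (int)mloc[r].size();
    if (t == T) {
      mloc[r].push_back(0);
      nloc[r].push_back(0);
      l1[r].push_back(std::vector<double>(M, 0.0));
      l2[r].push_back(std::vector<double>(M, 0.0));
    }
    L[r][q] = t;
    mloc[r][t]++; nloc[r][t] += csize[q];
    for (int j = 0; j < M; ++j) {
      l1[r][t][j] += g1[q][j];
      l2[r][t][j] += g2[q][j];
    }
  }

  // ---- Gibbs updates ----

  // per-context log weights for locally allocating a singleton gene i whose
  // cluster is new; fills w (length T_r + 1, unnormalized)
  void new_cluster_local_weights(int i, int r, std::vector<double>& w) const {
    int T = (int)mloc[r].size();
    int q = Q();                 // existing clusters, new one excluded
    w.assign(T + 1, 0.0);
    for (int t = 0; t < T; ++t) {
      double lw = std::log((double)mloc[r][t]) - std::log(q + phi);
      if (!prior_only)
        for (int j = 0; j < M; ++j)
          if (D[j] == r)
            lw += logpred_dim(X(i, j), nloc[r][t], l1[r][t][j], l2[r][t][j], j);
      w[t] = lw;
    }
    double lw = std::log(phi) - std::log(q + phi);
    if (!prior_only)
      for (int j = 0; j < M; ++j)
        if (D[j] == r) lw += logpred_dim(X(i, j), 0.0, 0.0, 0.0, j);
    w[T] = lw;
  }

  void update_gene(int i) {
    remove_gene(i);
    int q = Q(), R0 = R();
    std::vector<double> logw(q + 1);
    for (int k = 0; k < q; ++k) {
      double lw = std::log((double)csize[k]);
      if (!prior_only)
        for (int j = 0; j < M; ++j) {
          int r = D[j], t = L[r][k];
          lw += logpred_dim(X(i, j), nloc[r][t], l1[r][t][j], l2[r][t][j], j);
        }
      logw[k] = lw;
    }
    // new global cluster: local allocation marginalized per context
    double lwnew = std::log(alpha);
    std::vector<std::vector<double> > locw(R0);
    for (int r = 0; r < R0; ++r) {
      new_cluster_local_weights(i, r, locw[r]);
      lwnew += log_sum_exp(locw[r]);
    }
    logw[q] = lwnew;
    int pick = gumbel_max(logw);
    if (pick < q) {
      add_gene(i, pick);
    } else {
      // create singleton cluster, then draw its local label in each context
      csize.push_back(0);
      g1.push_back(std::vector<double>(M, 0.0));
      g2.push_back(std::vector<double>(M, 0.0));
      for (int r = 0; r < R0; ++r) L[r].push_back(-1);
      C[i] = q;
      csize[q] = 1;
      for (int j = 0; j < M; ++j) {
        double x = X(i, j);
        g1[q][j] = x; g2[q][j] = x * x;
      }
      for (int r = 0; r < R0; ++r) {
        int t = gumbel_max(locw[r]);
        attach_local(r, q, t);
      }
    }
  }

  void update_local(int q, int r) {
    int t0 = L[r][q];
    mloc[r][t0]--; nloc[r][t0] -= csize[q];
    for (int j = 0; j < M; ++j) {
      l1[r][t0][j] -= g1[q][j];
      l2[r][t0][j] -= g2[q][j];
    }
    L[r][q] = -1;
    if (mloc[r][t0] == 0) delete_local(r, t0);
    int T = (int)mloc[r].size();
    std::vector<double> w(T + 1);
    for (int t = 0; t < T; ++t) {
      double lw = std::log((double)mloc[r][t]);
      if (!prior_only)
        for (int j = 0; j < M; ++j)
          if (D[j] == r)
            lw += logm_dim(nloc[r][t] + csize[q],
                           l1[r][t][j] + g1[q][j],
                           l2[r][t][j] + g2[q][j], j)
                - logm_dim(nloc[r][t], l1[r][t][j], l2[r][t][j], j);
      w[t] = lw;
    }
    double lw = std::log(phi);
    if (!prior_only)
      for (int j = 0; j < M; ++j)
        if (D[j] == r) lw += logm_dim(csize[q], g1[q][j], g2[q][j], j);
    w[T] = lw;
    attach_local(r, q, gumbel_max(w));
  }

  void delete_context(int r0) {
    dsize.erase(dsize.begin() + r0);
    L.erase(L.begin() + r0);
    mloc.erase(mloc.begin() + r0);
    nloc.erase(nloc.begin() + r0);
    l1.erase(l1.begin() + r0);
    l2.erase(l2.begin() + r0);
    for (int j = 0; j < M; ++j) if (D[j] > r0) D[j]--;
  }

  // marginal log likelihood of sample dimension j under a partition of the
  // current global clusters (used for new-context candidates)
  double partition_loglik_dim(const std::vector<int>& part, int j) const {
    int q = Q();
    int T = 0;
    for (int k = 0; k < q; ++k) if (part[k] + 1 > T) T = part[k] + 1;
    std::vector<double> n(T, 0.0), s1(T, 0.0), s2(T, 0.0);
    for (int k = 0; k < q; ++k) {
      int t = part[k];
      n[t] += csize[k]; s1[t] += g1[k][j]; s2[t] += g2[k][j];
    }
    double lw = 0.0;
    for (int t = 0; t < T; ++t) lw += logm_dim(n[t], s1[t], s2[t], j);
    return lw;
  }

  // Sample-to-context move.  New-context candidates follow the
  // auxiliary-component scheme for non-conjugate DP mixtures: aux_m candidate
  // contexts carry local partitions drawn from the CRP(phi) prior (the
  // partition of a just-emptied context is retained as one auxiliary), each
  // entering with prior mass beta / aux_m.
  void update_context(int j) {
    int r0 = D[j];
    D[j] = -1;
    dsize[r0]--;
    std::vector<std::vector<int> > aux(aux_m);
    int q = Q();
    bool have_old = false;
    std::vector<int> old_part;
    if (dsize[r0] == 0) {
      old_part = L[r0];
      have_old = true;
      delete_context(r0);
    }
    int R0 = R();
    for (int h = 0; h < aux_m; ++h) {
      if (h == 0 && have_old) aux[h] = old_part;
      else aux[h] = crp_partition(q, phi);
    }
    std::vector<double> w(R0 + aux_m);
    for (int r = 0; r < R0; ++r) {
      double lw = std::log((double)dsize[r]);
      if (!prior_only) {
        int T = (int)mloc[r].size();
        for (int t = 0; t < T; ++t)
          lw += logm_dim(nloc[r][t], l1[r][t][j], l2[r][t][j], j);
      }
      w[r] = lw;
    }
    for (int h = 0; h < aux_m; ++h) {
      double lw = std::log(beta / aux_m);
      if (!prior_only) lw += partition_loglik_dim(aux[h], j);
      w[R0 + h] = lw;
    }
    int pick = gumbel_max(w);
    if (pick < R0) {
      D[j] = pick;
      dsize[pick]++;
    } else {
      dsize.push_back(1);
      L.push_back(std::vector<int>());
      mloc.push_back(std::vector<int>());
      nloc.push_back(std::vector<int>());
      l1.push_back(std::vector<std::vector<double> >());
      l2.push_back(std::vector<std::vector<double> >());
      D[j] = R0;
      local_from_partition(R0, aux[pick - R0]);
    }
  }

  // ---- consistency check: rebuild all statistics from scratch ----
  double max_stat_error() const {
    double err = 0.0;
    int q = Q();
    std::vector<std::vector<double> > G1(q, std::vector<double>(M, 0.0));
    std::vector<std::vector<double> > G2(q, std::vector<double>(M, 0.0));
    std::vector<int> CS(q, 0);
    for (int i = 0; i < N; ++i) {
      CS[C[i]]++;
      for (int j = 0; j < M; ++j) {
        double x = X(i, j);
        G1[C[i]][j] += x; G2[C[i]][j] += x * x;
      }
    }
    for (int k = 0; k < q; ++k) {
      err = std::max(err, std::fabs((double)(CS[k] - csize[k])));
      for (int j = 0; j < M; ++j) {
        err = std::max(err, std::fabs(G1[k][j] - g1[k][j]));
        err = std::max(err, std::fabs(G2[k][j] - g2[k][j]));
      }
    }
    for (int r = 0; r < R(); ++r) {
      int T = (int)mloc[r].size();
      std::vector<int> ML(T, 0), NL(T, 0);
      std::vector<std::vector<double> > S1(T, std::vector<double>(M, 0.0));
      std::vector<std::vector<double> > S2(T, std::vector<double>(M, 0.0));
      for (int k = 0; k < q; ++k) {
        int t = L[r][k];
        ML[t]++; NL[t] += CS[k];
        for (int j = 0; j < M; ++j) {
          S1[t][j] += G1[k][j]; S2[t][j] += G2[k][j];
        }
      }
      for (int t = 0; t < T; ++t) {
        err = std::max(err, std::fabs((double)(ML[t] - mloc[r][t])));
        err = std::max(err, std::fabs((double)(NL[t] - nloc[r][t])));
        for (int j = 0; j < M; ++j) {
          err = std::max(err, std::fabs(S1[t][j] - l1[r][t][j]));
          err = std::max(err, std::fabs(S2[t][j] - l2[r][t][j]));
        }
      }
    }
    return err;
  }

  void rebuild_stats() {
    int q = Q();
    for (int k = 0; k < q; ++k) {
      std::fill(g1[k].begin(), g1[k].end(), 0.0);
      std::fill(g2[k].begin(), g2[k].end(), 0.0);
    }
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < M; ++j) {
        double x = X(i, j);
        g1[C[i]][j] += x; g2[C[i]][j] += x * x;
      }
    for (int r = 0; r < R(); ++r) {
      int T = (int)mloc[r].size();
      for (int t = 0; t < T; ++t) {
        std::fill(l1[r][t].begin(), l1[r][t].end(), 0.0);
        std::fill(l2[r][t].begin(), l2[r][t].end(), 0.0);
      }
      for (int k = 0; k < q; ++k) {
        int t = L[r][k];
        for (int j = 0; j < M; ++j) {
          l1[r][t][j] += g1[k][j]; l2[r][t][j] += g2[k][j];
        }
      }
    }
  }
};

// ---------------------------------------------------------------------------
// DP concentration resampling (Escobar-West auxiliary-variable scheme,
// Gamma(shape, rate) hyperprior); multi-group extension for phi.
// ---------------------------------------------------------------------------

static double escobar_west(double conc, int k, int n,
                           double shape, double rate) {
  if (n <= 0 || k <= 0) return conc;
  double eta = R::rbeta(conc + 1.0, (double)n);
  double odds = (shape + k - 1.0) / ((double)n * (rate - std::log(eta)));
  double pi1 = odds / (1.0 + odds);
  double sh = (unif_rand() < pi1) ? shape + k : shape + k - 1.0;
  return R::rgamma(sh, 1.0 / (rate - std::log(eta)));
}

// multi-restaurant version: each group g has n_customers[g] items at
// k_tables[g] tables sharing one concentration.
static double escobar_west_multi(double conc, const std::vector<int>& k_tables,
                                 const std::vector<int>& n_customers,
                                 double shape, double rate) {
  double sh = shape, rt = rate;
  for (size_t g = 0; g < k_tables.size(); ++g) {
    int n = n_customers[g];
    if (n <= 0) continue;
    double eta = R::rbeta(conc + 1.0, (double)n);
    rt -= std::log(eta);
    double p = (double)n / ((double)n + conc);
    double s = (unif_rand() < p) ? 1.0 : 0.0;
    sh += k_tables[g] - s;
  }
  return R::rgamma(sh, 1.0 / rt);
}

// [[Rcpp::export(name = ".dp_conc_draw_cpp")]]
double dp_conc_draw_cpp(double conc, int k, int n, double shape, double rate) {
  return escobar_west(conc, k, n, shape, rate);
}

// ---------------------------------------------------------------------------
// chain driver
// ---------------------------------------------------------------------------

static void accumulate_pairs(const std::vector<int>& labels, IntegerMatrix& M) {
  int n = (int)labels.size();
  for (int i = 0; i < n; ++i) {
    M(i, i) += 1;
    for (int k = i + 1; k < n; ++k)
      if (labels[i] == labels[k]) { M(i, k) += 1; M(k, i) += 1; }
  }
}

// [[Rcpp::export(name = ".dcim_chain_cpp")]]
List dcim_chain_cpp(NumericMatrix X,
                    NumericVector m0, double lambda, double a, double tau,
                    double alpha, double beta, double phi,
                    int n_burnin, int n_keep, int thin,
                    IntegerVector fixed_contexts,
                    bool prior_only,
                    bool resample_conc,
                    std::string track_local,  // "context", "sample", "none"
                    int aux_m,
                    bool debug_checks) {
  State st(X);
  st.m0 = as<std::vector<double> >(m0);
  st.lambda = lambda; st.a = a; st.tau = tau;
  st.alpha = alpha; st.beta = beta; st.phi = phi;
  st.prior_only = prior_only;
  st.fixed_D = (fixed_contexts.size() == st.M);
  st.aux_m = aux_m;
  st.init(fixed_contexts);

  int N = st.N, M = st.M;
  IntegerMatrix co_gene(N, N), co_sample(M, M);
  std::vector<IntegerMatrix> co_local;
  int n_local_mats = 0;
  if (track_local == "context") {
    n_local_mats = st.fixed_D ? st.R() : 0;
    if (!st.fixed_D)
      stop("track_local = 'context' requires fixed_contexts");
  } else if (track_local == "sample") {
    n_local_mats = M;
  }
  for (int k = 0; k < n_local_mats; ++k)
    co_local.push_back(IntegerMatrix(N, N));

  int n_draws = (n_keep + thin - 1) / thin;
  List draws(n_draws);
  int draw_idx = 0;
  std::vector<double> alpha_trace, beta_trace, phi_trace;
  double max_err = 0.0;
  int total = n_burnin + n_keep;
  std::vector<int> loc_label(N);

  for (int sweep = 0; sweep < total; ++sweep) {
    for (int i = 0; i < N; ++i) st.update_gene(i);
    for (int r = 0; r < st.R(); ++r)
      for (int q = 0; q < st.Q(); ++q) st.update_local(q, r);
    if (!st.fixed_D)
      for (int j = 0; j < M; ++j) st.update_context(j);
    if (resample_conc) {
      st.alpha = escobar_west(st.alpha, st.Q(), N, 1.0, 1.0);
      st.beta  = escobar_west(st.beta, st.R(), M, 1.0, 1.0);
      std::vector<int> kt(st.R()), nc(st.R(), st.Q());
      for (int r = 0; r < st.R(); ++r) kt[r] = (int)st.mloc[r].size();
      st.phi = escobar_west_multi(st.phi, kt, nc, 1.0, 1.0);
    }
    if (debug_checks) max_err = std::max(max_err, st.max_stat_error());
    if ((sweep + 1) % 100 == 0) st.rebuild_stats();

    if (sweep >= n_burnin) {
      accumulate_pairs(st.C, co_gene);
      accumulate_pairs(st.D, co_sample);
      if (track_local == "context") {
        for (int r = 0; r < st.R(); ++r) {
          for (int i = 0; i < N; ++i) loc_label[i] = st.L[r][st.C[i]];
          accumulate_pairs(loc_label, co_local[r]);
        }
      } else if (track_local == "sample") {
        for (int j = 0; j < M; ++j) {
          int r = st.D[j];
          for (int i = 0; i < N; ++i) loc_label[i] = st.L[r][st.C[i]];
          accumulate_pairs(loc_label, co_local[j]);
        }
      }
      int kept = sweep - n_burnin;
      if (kept % thin == 0) {
        List Lout(st.R());
        for (int r = 0; r < st.R(); ++r) {
          IntegerVector lr(st.Q());
          for (int q = 0; q < st.Q(); ++q) lr[q] = st.L[r][q] + 1;
          Lout[r] = lr;
        }
        IntegerVector Cd(N), Dd(M);
        for (int i = 0; i < N; ++i) Cd[i] = st.C[i] + 1;
        for (int j = 0; j < M; ++j) Dd[j] = st.D[j] + 1;
        draws[draw_idx++] = List::create(_["C"] = Cd, _["D"] = Dd, _["L"] = Lout);
        alpha_trace.push_back(st.alpha);
        beta_trace.push_back(st.beta);
        phi_trace.push_back(st.phi);
      }
    }
  }

  List co_local_out(n_local_mats);
  for (int k = 0; k < n_local_mats; ++k) co_local_out[k] = co_local[k];

  return List::create(
    _["co_gene_counts"] = co_gene,
    _["co_sample_counts"] = co_sample,
    _["co_local_counts"] = co_local_out,
    _["n_kept"] = n_keep,
    _["kept_draws"] = draws,
    _["alpha_trace"] = wrap(alpha_trace),
    _["beta_trace"] = wrap(beta_trace),
    _["phi_trace"] = wrap(phi_trace),
    _["max_stat_error"] = max_err);
}
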