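#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Soft-threshold operator.
static inline double soft(double z, double lambda) {
  if (z > lambda) return z - lambda;
  if (z < -lambda) return z + lambda;
  return 0.0;
}

// Core path solver: L1-penalized logistic regression over a descending
// lambda sequence by cyclic coordinate descent. Each coordinate visit takes
// a damped Newton step on a local quadratic approximation of the negative
// log-likelihood (curvature (1/n) sum x^2 p(1-p), floored, per-visit step
// bounded so the iteration stays stable when fitted probabilities
// saturate). The intercept is unpenalized; coefficients are clamped to
// [-cap, cap] against perfect separation at small lambda. Predictors are
// binary and stored as row-index lists, so a coordinate visit costs
// O(#ones); applying an accepted step uses a single exp() via the identity
// p' = p e^d / (1 + p (e^d - 1)). Warm starts carry the solution down the
// path; after each full sweep the active set is cycled to convergence, then
// the full set is re-checked (KKT). Fitted probabilities are recomputed from
// eta at the end of every lambda, in the same pass that evaluates the
// log-likelihood.
static void solve_path(int n, int q, const std::vector<const std::vector<int>*>& nz,
                       const double* y, const double* wt /* row multiplicities */,
                       const std::vector<double>& lambdas,
                       double tol, int max_iter, double cap,
                       double* beta /* (q+1) x L, column-major */,
                       double* loglik, int* df, int* cap_hit) {
  const double hfloor = 1e-4, step_max = 2.0, step_min = tol * 0.1;
  const int L = (int)lambdas.size();
  const int m = n;  // rows after aggregation; n enters through the weights
  std::vector<double> b(q, 0.0), eta(m, 0.0), pr(m, 0.5);
  std::vector<double> ysum(q);
  double b0 = 0.0, ytot = 0.0, wtot = 0.0;
  for (int i = 0; i < m; ++i) { ytot += wt[i] * y[i]; wtot += wt[i]; }
  for (int k = 0; k < q; ++k) {
    double s = 0.0;
    for (int i : *nz[k]) s += wt[i] * y[i];
    ysum[k] = s;
  }

  // one exp() per accepted step; the probability update uses the exact
  // identity p' = p e^d / (1 + p (e^d - 1))
  auto apply_all = [&](double d) {
    const double ed = std::exp(d);
    for (int i = 0; i < m; ++i) {
      eta[i] += d;
      pr[i] = pr[i] * ed / (1.0 + pr[i] * (ed - 1.0));
    }
  };
  auto apply_col = [&](int k, double d) {
    const double ed = std::exp(d);
    for (int i : *nz[k]) {
      eta[i] += d;
      pr[i] = pr[i] * ed / (1.0 + pr[i] * (ed - 1.0));
    }
  };

  auto update_intercept = [&]() -> double {
    double sp = 0.0, sh = 0.0;
    for (int i = 0; i < m; ++i) {
      sp += wt[i] * pr[i];
      sh += wt[i] * pr[i] * (1.0 - pr[i]);
    }
    double g = (sp - ytot) / wtot, h = sh / wtot;
    if (h < hfloor) h = hfloor;
    double d = -g / h;
    if (d > step_max) d = step_max;
    if (d < -step_max) d = -step_max;
    double bn = b0 + d;
    if (bn > cap) bn = cap;
    if (bn < -cap) bn = -cap;
    d = bn - b0;
    if (std::abs(d) < step_min) return 0.0;  // sub-tolerance: not worth a full pass
    b0 = bn; apply_all(d);
    return std::abs(d);
  };

  auto update_slope = [&](int k, double lam) -> double {
    if (nz[k]->empty()) return 0.0;
    double sp = 0.0, sh = 0.0;
    for (int i : *nz[k]) {
      sp += wt[i] * pr[i];
      sh += wt[i] * pr[i] * (1.0 - pr[i]);
    }
    double g = (sp - ysum[k]) / wtot, h = sh / wtot;
    if (h < hfloor) h = hfloor;
    double bn = soft(b[k] * h - g, lam) / h;
    double d = bn - b[k];
    if (d > step_max) d = step_max;
    if (d < -step_max) d = -step_max;
    bn = b[k] + d;
    if (bn > cap) bn = cap;
    if (bn < -cap) bn = -cap;
    d = bn - b[k];
    if (b[k] != 0.0 && std::abs(d) < step_min) return 0.0;
    if (d != 0.0) { b[k] = bn; apply_col(k, d); }
    return std::abs(d);
  };

  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    int it = 0;
    while (it < max_iter) {
      double delta_max = update_intercept();
      for (int k = 0; k < q; ++k) {
        double d = update_slope(k, lam);
        if (d > delta_max) delta_max = d;
      }
      ++it;
      if (delta_max < tol) break;
      while (it < max_iter) {  // inner cycles on the active set
        double dm = update_intercept();
        for (int k = 0; k < q; ++k) {
          if (b[k] == 0.0) continue;
          double d = update_slope(k, lam);
          if (d > dm) dm = d;
        }
        ++it;
        if (dm < tol) break;
      }
    }

    // exact refresh of pr and the log-likelihood in one pass
    double ll = 0.0;
    for (int i = 0; i < m; ++i) {
      const double e = eta[i];
      double lse;
      if (e > 0) {
        const double ex = std::exp(-e);
        pr[i] = 1.0 / (1.0 + ex);
        lse = e + std::log1p(ex);
      } else {
        const double ex = std::exp(e);
        pr[i] = ex / (1.0 + ex);
        lse = std::log1p(ex);
      }
      ll += wt[i] * (y[i] * e - lse);
    }
    loglik[l] = ll;
    double* bl = beta + (size_t)(q + 1) * l;
    bl[0] = b0;
    int nzc = 0;
    int hit = std::abs(b0) >= cap;
    for (int k = 0; k < q; ++k) {
      bl[k + 1] = b[k];
      if (b[k] != 0.0) ++nzc;
      if (std::abs(b[k]) >= cap) hit = 1;
    }
    df[l] = nzc;
    cap_hit[l] = hit;
  }
}

static std::vector<double> log_spaced(double lam_max, double ratio, int n_lambda) {
  std::vector<double> lam(n_lambda);
  if (n_lambda == 1) { lam[0] = lam_max; return lam; }
  const double l0 = std::log(lam_max), l1 = std::log(ratio * lam_max);
  for (int i = 0; i < n_lambda; ++i)
    lam[i] = std::exp(l0 + (l1 - l0) * i / (n_lambda - 1));
  return lam;
}

// Single-response path fit (exported surface behind fit_penalized_logistic).
// [[Rcpp::export]]
List cd_logistic_path(const NumericVector& y, const NumericMatrix& X,
                      const NumericVector& lambdas, double tol, int max_iter,
                      double cap) {
  const int n = X.nrow(), q = X.ncol(), L = lambdas.size();
  std::vector<std::vector<int>> nzs(q);
  for (int k = 0; k < q; ++k)
    for (int i = 0; i < n; ++i)
      if (X(i, k) != 0.0) nzs[k].push_back(i);
  std::vector<const std::vector<int>*> nz(q);
  for (int k = 0; k < q; ++k) nz[k] = &nzs[k];

  NumericMatrix beta(q + 1, L);
  NumericVector loglik(L);
  IntegerVector df(L), hit(L);
  std::vector<double> wt(n, 1.0);
  solve_path(n, q, nz, &y[0], wt.data(), as<std::vector<double>>(lambdas), tol,
             max_iter, cap, beta.begin(), loglik.begin(), df.begin(), hit.begin());
  LogicalVector cap_hit(L);
  for (int l = 0; l < L; ++l) cap_hit[l] = hit[l] != 0;
  return List::create(_["beta"] = beta, _["loglik"] = loglik, _["df"] = df,
                      _["cap_hit"] = cap_hit);
}

// Whole-network eLasso: every node regressed on all others along its own
// penalty path, penalty chosen per node by minimizing
// EBIC = -2 ll + df log(n) + 2 gamma df log(p - 1)
// (ties resolve to the sparser, larger penalty). Shares solve_path with the
// single-response surface. Constant response columns are flagged and left
// with no neighbors.
// [[Rcpp::export]]
List ising_elasso(const IntegerMatrix& X, double gamma, int n_lambda,
                  double ratio, double tol, int max_iter, double cap) {
  const int n = X.nrow(), p = X.ncol();

  // collapse duplicate response patterns: binary panels repeat rows heavily,
  // and the likelihood only depends on pattern counts
  int m = n;
  std::vector<int> row_of;        // unique-row index per original row
  std::vector<double> wt;         // multiplicity per unique row
  std::vector<int> rep_row;       // one original row per unique row
  if (p <= 64) {
    std::unordered_map<uint64_t, int> seen;
    row_of.resize(n);
    for (int i = 0; i < n; ++i) {
      uint64_t key = 0;
      for (int k = 0; k < p; ++k) key = (key << 1) | (uint64_t)(X(i, k) != 0);
      auto it = seen.find(key);
      if (it == seen.end()) {
        const int id = (int)rep_row.size();
        seen.emplace(key, id);
        rep_row.push_back(i);
        wt.push_back(1.0);
        row_of[i] = id;
      } else {
        wt[it->second] += 1.0;
        row_of[i] = it->second;
      }
    }
    m = (int)rep_row.size();
  } else {
    rep_row.resize(n);
    wt.assign(n, 1.0);
    for (int i = 0; i < n; ++i) rep_row[i] = i;
  }

  std::vector<std::vector<int>> nzs(p);       // over unique rows
  std::vector<double> colsum(p, 0.0);         // weighted: counts over original rows
  for (int k = 0; k < p; ++k)
    for (int u = 0; u < m; ++u)
      if (X(rep_row[u], k) != 0) { nzs[k].push_back(u); colsum[k] += wt[u]; }

  NumericMatrix nodewise(p, p);
  NumericVector tau(p), sel_lambda(p);
  LogicalVector constant(p), cap_sel(p);
  std::vector<double> y(m), loglik(n_lambda);
  std::vector<double> beta((size_t)p * n_lambda);
  std::vector<int> df(n_lambda), hit(n_lambda);

  for (int j = 0; j < p; ++j) {
    if (colsum[j] == 0.0 || colsum[j] == (double)n) {
      constant[j] = true;
      double m = (colsum[j] + 0.5) / (n + 1.0);  // placeholder; R side sets tau
      tau[j] = std::log(m / (1.0 - m));
      sel_lambda[j] = NA_REAL;
      continue;
    }
    for (int u = 0; u < m; ++u) y[u] = X(rep_row[u], j);
    const double ybar = colsum[j] / n;
    std::vector<const std::vector<int>*> nz;
    std::vector<int> pred;
    nz.reserve(p - 1); pred.reserve(p - 1);
    double lam_max = 0.0;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      double s = 0.0;
      for (int u : nzs[k]) s += wt[u] * y[u];
      const double sc = std::abs(s - ybar * colsum[k]) / n;
      if (sc > lam_max) lam_max = sc;
      nz.push_back(&nzs[k]);
      pred.push_back(k);
    }
    if (lam_max <= 0.0) lam_max = 1e-4;  // all predictors constant
    std::vector<double> lambdas = log_spaced(lam_max, ratio, n_lambda);
    const int q = (int)nz.size();
    solve_path(m, q, nz, y.data(), wt.data(), lambdas, tol, max_iter, cap,
               beta.data(), loglik.data(), df.data(), hit.data());
    int best = 0;
    double best_score = R_PosInf;
    for (int l = 0; l < n_lambda; ++l) {
      const double score = -2.0 * loglik[l] + df[l] * std::log((double)n) +
        2.0 * gamma * df[l] * std::log((double)q);
      if (score < best_score) { best_score = score; best = l; }
    }
    const double* bl = beta.data() + (size_t)(q + 1) * best;
    tau[j] = bl[0];
    for (int a = 0; a < q; ++a) nodewise(j, pred[a]) = bl[a + 1];
    sel_lambda[j] = lambdas[best];
    cap_sel[j] = hit[best] != 0;
  }

  return List::create(_["nodewise"] = nodewise, _["tau"] = tau,
                      _["selected_lambda"] = sel_lambda,
                      _["constant"] = constant, _["cap_hit"] = cap_sel);
}
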