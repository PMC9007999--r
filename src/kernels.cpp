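// Statistical and search kernels for Gaussian Bayesian network learning.
//
// All functions take the MLE covariance matrix S (cross-products / n) of the
// (column-wise centred) data and the number of observations n.  Working from
// moments rather than raw data makes each score or conditional-independence
// test a small linear solve, which is what allows bootstrap ensembles of
// thousands of structure learns to run in seconds.

#include <RcppArmadillo.h>
#include <deque>
#include <unordered_map>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double VAR_FLOOR = 1e-12;   // residual-variance guard
static const double EPS_IMPROVE = 1e-10; // strict-improvement margin

// residual variance of `child` regressed on `parents` (intercept implicit:
// S is centred), floored at VAR_FLOOR.  Returns -1 on singular design.
static double residual_variance(const arma::mat& S, int child,
                                const arma::uvec& parents) {
  double v = S(child, child);
  if (parents.n_elem > 0) {
    arma::mat Spp = S.submat(parents, parents);
    arma::uvec c1 = {static_cast<arma::uword>(child)};
    arma::vec spc = S.submat(parents, c1);
    arma::vec b;
    if (!arma::solve(b, Spp, spc, arma::solve_opts::no_approx))
      return -1.0;
    v -= arma::dot(spc, b);
  }
  if (v < VAR_FLOOR) v = VAR_FLOOR;
  return v;
}

// Gaussian BIC score of child | parents: profiled log-likelihood minus
// (k/2) log(n) with k = |parents| + 2 (intercept + residual variance).
static double node_score(const arma::mat& S, double n, int child,
                         const arma::uvec& parents) {
  double v = residual_variance(S, child, parents);
  if (v < 0) return -std::numeric_limits<double>::infinity();
  double loglik = -0.5 * n * (std::log(2.0 * M_PI * v) + 1.0);
  double k = static_cast<double>(parents.n_elem) + 2.0;
  return loglik - 0.5 * k * std::log(n);
}

// [[Rcpp::export]]
double cpp_node_score(const arma::mat& S, double n, int child,
                      const arma::uvec& parents) {
  return node_score(S, n, child, parents);
}

// partial correlation of x and y given Z, from the covariance matrix.
// Equals the Pearson correlation of the residuals of x and y after
// projection on Z (with intercept).  Degenerate (zero residual variance)
// margins give r = 0.
static double pcor_from_cov(const arma::mat& S, int x, int y,
                            const arma::uvec& Z) {
  double sxx = S(x, x), syy = S(y, y), sxy = S(x, y);
  if (Z.n_elem > 0) {
    arma::mat Szz = S.submat(Z, Z);
    arma::uvec xi = {static_cast<arma::uword>(x)};
    arma::uvec yi = {static_cast<arma::uword>(y)};
    arma::vec szx = S.submat(Z, xi);
    arma::vec szy = S.submat(Z, yi);
    arma::vec bx, by;
    if (!arma::solve(bx, Szz, szx, arma::solve_opts::no_approx) ||
        !arma::solve(by, Szz, szy, arma::solve_opts::no_approx))
      Rcpp::stop("singular conditioning design in partial correlation");
    sxx -= arma::dot(szx, bx);
    syy -= arma::dot(szy, by);
    sxy -= arma::dot(szx, by);
  }
  if (sxx < VAR_FLOOR || syy < VAR_FLOOR) return 0.0;
  double r = sxy / std::sqrt(sxx * syy);
  if (r > 1.0) r = 1.0;
  if (r < -1.0) r = -1.0;
  return r;
}

// two-sided p-value of the exact t-test for a (partial) correlation with
// df = n - |Z| - 2.  |r| = 1 underflows to the smallest positive double.
static double pcor_pvalue(double r, double n, int nz) {
  double df = n - nz - 2.0;
  if (df < 1.0) Rcpp::stop("exact t-test requires n - |Z| - 2 >= 1");
  double a = 1.0 - r * r;
  if (a <= 0.0) return std::numeric_limits<double>::min();
  double t = std::fabs(r) * std::sqrt(df / a);
  double p = 2.0 * R::pt(-t, df, 1, 0);
  if (p <= 0.0) p = std::numeric_limits<double>::min();
  if (p > 1.0) p = 1.0;
  return p;
}

// [[Rcpp::export]]
List cpp_pcor_test(const arma::mat& S, double n, int x, int y,
                   const arma::uvec& Z) {
  double r = pcor_from_cov(S, x, y, Z);
  double p = pcor_pvalue(r, n, static_cast<int>(Z.n_elem));
  return List::create(_["r"] = r, _["p"] = p);
}

// [[Rcpp::export]]
double cpp_exact_t_pvalue(double r, double n, int nz) {
  return pcor_pvalue(r, n, nz);
}

// maximum p-value of the test x _||_ y | Z over all subsets Z of `cpc`
// with |Z| <= max_z (the empty set included).  This is the "min association"
// of the max-min family.  Early exit once the running maximum exceeds
// `alpha`: the pair is then separable and the exact maximum is not needed.
// [[Rcpp::export]]
double cpp_worst_pvalue(const arma::mat& S, double n, int x, int y,
                        const arma::uvec& cpc, int max_z, double alpha) {
  int m = static_cast<int>(cpc.n_elem);
  if (max_z > m) max_z = m;
  double worst = 0.0;
  unsigned long n_subsets = 1UL << m;
  for (unsigned long mask = 0; mask < n_subsets; ++mask) {
    int sz = __builtin_popcountl(mask);
    if (sz > max_z) continue;
    arma::uvec Z(sz);
    int k = 0;
    for (int b = 0; b < m; ++b)
      if (mask & (1UL << b)) Z[k++] = cpc[b];
    double df = n - sz - 2.0;
    if (df < 1.0) continue;
    double p = pcor_pvalue(pcor_from_cov(S, x, y, Z), n, sz);
    if (p > worst) {
      worst = p;
      if (worst > alpha) return worst;
    }
  }
  return worst;
}

// ---- hill climbing / tabu search ------------------------------------------

struct ScoreCache {
  const arma::mat& S;
  double n;
  std::unordered_map<uint64_t, double> cache;
  ScoreCache(const arma::mat& S_, double n_) : S(S_), n(n_) {}
  double get(int child, const std::vector<int>& parents) {
    uint64_t key = static_cast<uint64_t>(child) << 58;
    for (int p : parents) key |= (1ULL << p);
    auto it = cache.find(key);
    if (it != cache.end()) return it->second;
    arma::uvec pv(parents.size());
    for (size_t i = 0; i < parents.size(); ++i) pv[i] = parents[i];
    double s = node_score(S, n, child, pv);
    cache[key] = s;
    return s;
  }
};

static std::vector<int> get_parents(const arma::imat& amat, int child) {
  std::vector<int> out;
  int p = amat.n_rows;
  for (int i = 0; i < p; ++i)
    if (amat(i, child) == 1) out.push_back(i);
  return out;
}

// is there a directed path from `from` to `to`?
static bool path_exists(const arma::imat& amat, int from, int to) {
  int p = amat.n_rows;
  if (from == to) return true;
  std::vector<char> seen(p, 0);
  std::vector<int> stack = {from};
  seen[from] = 1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    for (int w = 0; w < p; ++w) {
      if (amat(v, w) == 1 && !seen[w]) {
        if (w == to) return true;
        seen[w] = 1;
        stack.push_back(w);
      }
    }
  }
  return false;
}

static double total_score(ScoreCache& sc, const arma::imat& amat) {
  double s = 0.0;
  int p = amat.n_rows;
  for (int j = 0; j < p; ++j) s += sc.get(j, get_parents(amat, j));
  return s;
}

// Greedy score-based search over DAGs with add / delete / reverse moves.
// forbid(i,j) = 1  : arc i->j may never be present (blacklist, or outside a
//                    restricted skeleton in hybrid search).
// wl(i,j)     = 1  : arc i->j is fixed (whitelist); never deleted/reversed.
// start            : initial adjacency matrix (must already contain wl).
// tabu_len = 0     : plain hill climbing (stop at first local optimum).
// tabu_len > 0     : tabu search keeping the last tabu_len visited graphs
//                    forbidden; up to max_worse non-improving moves; the
//                    best graph visited is returned.
// Ties between moves are broken deterministically by enumeration order
// (adds, then deletes, then reversals; row-major within each).
// [[Rcpp::export]]
arma::imat cpp_hc(const arma::mat& S, double n, const arma::imat& forbid,
                  const arma::imat& wl, const arma::imat& start,
                  int max_parents, int tabu_len, int max_worse,
                  int max_iter) {
  int p = S.n_rows;
  ScoreCache sc(S, n);
  arma::imat amat = start;
  std::vector<double> nscore(p);
  for (int j = 0; j < p; ++j) nscore[j] = sc.get(j, get_parents(amat, j));

  std::deque<arma::imat> tabu;   // recently visited graphs
  if (tabu_len > 0) tabu.push_back(amat);
  arma::imat best_amat = amat;
  double best_total = 0.0;
  for (int j = 0; j < p; ++j) best_total += nscore[j];
  double cur_total = best_total;
  int worse_streak = 0;

  auto in_tabu = [&](const arma::imat& g) {
    for (const arma::imat& t : tabu)
      if (arma::all(arma::vectorise(t == g))) return true;
    return false;
  };

  for (int iter = 0; iter < max_iter; ++iter) {
    double best_delta = -std::numeric_limits<double>::infinity();
    int b_i = -1, b_j = -1, b_op = -1; // 0 add, 1 delete, 2 reverse

    // candidate additions
    for (int i = 0; i < p; ++i) {
      for (int j = 0; j < p; ++j) {
        if (i == j || amat(i, j) == 1 || amat(j, i) == 1 || forbid(i, j) == 1)
          continue;
        std::vector<int> pj = get_parents(amat, j);
        if (max_parents > 0 && static_cast<int>(pj.size()) >= max_parents)
          continue;
        if (path_exists(amat, j, i)) continue; // would create a cycle
        std::vector<int> pj2 = pj;
        pj2.push_back(i);
        std::sort(pj2.begin(), pj2.end());
        double delta = sc.get(j, pj2) - nscore[j];
        if (delta > best_delta + EPS_IMPROVE) {
          if (tabu_len > 0) {
            arma::imat g = amat; g(i, j) = 1;
            if (in_tabu(g)) continue;
          }
          best_delta = delta; b_i = i; b_j = j; b_op = 0;
        }
      }
    }
    // candidate deletions
    for (int i = 0; i < p; ++i) {
      for (int j = 0; j < p; ++j) {
        if (amat(i, j) != 1 || wl(i, j) == 1) continue;
        std::vector<int> pj = get_parents(amat, j);
        pj.erase(std::remove(pj.begin(), pj.end(), i), pj.end());
        double delta = sc.get(j, pj) - nscore[j];
        if (delta > best_delta + EPS_IMPROVE) {
          if (tabu_len > 0) {
            arma::imat g = amat; g(i, j) = 0;
            if (in_tabu(g)) continue;
          }
          best_delta = delta; b_i = i; b_j = j; b_op = 1;
        }
      }
    }
    // candidate reversals
    for (int i = 0; i < p; ++i) {
      for (int j = 0; j < p; ++j) {
        if (amat(i, j) != 1 || wl(i, j) == 1 || forbid(j, i) == 1) continue;
        std::vector<int> pi = get_parents(amat, i);
        if (max_parents > 0 && static_cast<int>(pi.size()) >= max_parents)
          continue;
        arma::imat tmp = amat;
        tmp(i, j) = 0;
        if (path_exists(tmp, i, j)) continue; // another i~>j path: cycle
        std::vector<int> pj = get_parents(amat, j);
        pj.erase(std::remove(pj.begin(), pj.end(), i), pj.end());
        std::vector<int> pi2 = pi;
        pi2.push_back(j);
        std::sort(pi2.begin(), pi2.end());
        double delta = (sc.get(j, pj) - nscore[j]) +
                       (sc.get(i, pi2) - nscore[i]);
        if (delta > best_delta + EPS_IMPROVE) {
          if (tabu_len > 0) {
            arma::imat g = amat; g(i, j) = 0; g(j, i) = 1;
            if (in_tabu(g)) continue;
          }
          best_delta = delta; b_i = i; b_j = j; b_op = 2;
        }
      }
    }

    if (b_op < 0) break; // no admissible move at all
    if (tabu_len == 0 && best_delta <= EPS_IMPROVE) break; // local optimum

    // apply the move
    if (b_op == 0) {
      amat(b_i, b_j) = 1;
    } else if (b_op == 1) {
      amat(b_i, b_j) = 0;
    } else {
      amat(b_i, b_j) = 0;
      amat(b_j, b_i) = 1;
    }
    for (int j : {b_i, b_j}) nscore[j] = sc.get(j, get_parents(amat, j));
    cur_total += best_delta;

    if (tabu_len > 0) {
      tabu.push_back(amat);
      while (static_cast<int>(tabu.size()) > tabu_len) tabu.pop_front();
      if (cur_total > best_total + EPS_IMPROVE) {
        best_total = cur_total;
        best_amat = amat;
        worse_streak = 0;
      } else {
        if (++worse_streak > max_worse) break;
      }
    }
  }

  return (tabu_len > 0) ? best_amat : amat;
}

// [[Rcpp::export]]
bool cpp_path_exists(const arma::imat& amat, int from, int to) {
  return path_exists(amat, from, to);
}
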