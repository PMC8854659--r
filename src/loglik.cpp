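#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Shared pruning context: postorder edge arrays (1-based ape node ids; tips
// 1..ntip, root ntip+1), eigendecomposition of the normalized reversible
// rate matrix (Q = U diag(lam) Uinv), equilibrium frequencies, and an
// integer-coded alignment (0..3 = A,C,G,T; -1 = missing).
struct PruneCtx {
  std::vector<int> parent, child;
  std::vector<double> len;
  std::vector<bool> in_sub;
  double U[16], lam[4], Uinv[16], pi[4];
  int nnode, root, ntip, L;
  std::vector<int> data;              // ntip x L, column-major
  std::vector<int> noderow;           // node id -> data row (or -1)
  mutable std::vector<double> part;   // partial likelihood workspace
  mutable std::vector<bool> seen;

  PruneCtx(IntegerVector parent_, IntegerVector child_, NumericVector len_,
           LogicalVector in_sub_, NumericMatrix U_, NumericVector lam_,
           NumericMatrix Uinv_, NumericVector pi_, int nnode_, int root_,
           IntegerMatrix data_, IntegerVector tip_node_)
      : parent(parent_.begin(), parent_.end()),
        child(child_.begin(), child_.end()),
        len(len_.begin(), len_.end()),
        nnode(nnode_), root(root_), ntip(data_.nrow()), L(data_.ncol()),
        data(data_.begin(), data_.end()),
        noderow(nnode_ + 1, -1),
        part(4 * (nnode_ + 1)), seen(nnode_ + 1) {
    in_sub.assign(in_sub_.begin(), in_sub_.end());
    for (int i = 0; i < 4; ++i) {
      lam[i] = lam_[i];
      pi[i] = pi_[i];
      for (int j = 0; j < 4; ++j) {
        U[4 * i + j] = U_(i, j);
        Uinv[4 * i + j] = Uinv_(i, j);
      }
    }
    for (int r = 0; r < ntip; ++r) noderow[tip_node_[r]] = r;
  }

  mutable std::vector<std::array<double, 16>> P;
  mutable std::vector<double> t_cache;

  // log-likelihood of columns [c0, c1) at scales (s, rho); per-edge
  // transition matrices are cached on effective branch length, so passes
  // that vary only rho recompute only the subtree edges
  double loglik_range(double s, double rho, int c0, int c1,
                      double* percol = nullptr) const {
    const int nedge = parent.size();
    if ((int)P.size() != nedge) {
      P.assign(nedge, {});
      t_cache.assign(nedge, -1.0);
    }
    for (int e = 0; e < nedge; ++e) {
      const double t = len[e] * s * (in_sub[e] ? rho : 1.0);
      if (t == t_cache[e]) continue;
      t_cache[e] = t;
      if (t == 0.0) {  // exact identity: zero-length branches forbid change
        std::array<double, 16>& M = P[e];
        for (int i = 0; i < 16; ++i) M[i] = 0.0;
        M[0] = M[5] = M[10] = M[15] = 1.0;
        continue;
      }
      double el[4];
      for (int k = 0; k < 4; ++k) el[k] = std::exp(lam[k] * t);
      std::array<double, 16>& M = P[e];
      for (int i = 0; i < 4; ++i) {
        double rowsum = 0.0;
        for (int j = 0; j < 4; ++j) {
          double v = 0.0;
          for (int k = 0; k < 4; ++k) v += U[4 * i + k] * el[k] * Uinv[4 * k + j];
          if (v < 0.0) v = 0.0;
          M[4 * i + j] = v;
          rowsum += v;
        }
        for (int j = 0; j < 4; ++j) M[4 * i + j] /= rowsum;
      }
    }
    double total = 0.0;
    for (int col = c0; col < c1; ++col) {
      std::fill(seen.begin(), seen.end(), false);
      double logscale = 0.0;
      const int* dcol = &data[(size_t)col * ntip];
      for (int e = 0; e < (int)parent.size(); ++e) {
        const int p = parent[e], c = child[e];
        double* Lc = &part[4 * c];
        if (c <= ntip) {
          const int r = noderow[c];
          const int b = (r >= 0) ? dcol[r] : -1;
          if (b < 0) { Lc[0] = Lc[1] = Lc[2] = Lc[3] = 1.0; }
          else { Lc[0] = Lc[1] = Lc[2] = Lc[3] = 0.0; Lc[b] = 1.0; }
        }
        double* Lp = &part[4 * p];
        if (!seen[p]) { Lp[0] = Lp[1] = Lp[2] = Lp[3] = 1.0; seen[p] = true; }
        const std::array<double, 16>& M = P[e];
        double mx = 0.0;
        for (int i = 0; i < 4; ++i) {
          const double v = M[4 * i] * Lc[0] + M[4 * i + 1] * Lc[1] +
                           M[4 * i + 2] * Lc[2] + M[4 * i + 3] * Lc[3];
          Lp[i] *= v;
          if (Lp[i] > mx) mx = Lp[i];
        }
        if (mx > 0.0 && mx < 1e-200) {  // underflow guard for deep trees
          for (int i = 0; i < 4; ++i) Lp[i] /= mx;
          logscale += std::log(mx);
        }
      }
      const double* Lr = &part[4 * root];
      double lik = pi[0] * Lr[0] + pi[1] * Lr[1] + pi[2] * Lr[2] + pi[3] * Lr[3];
      const double ll = (lik > 0.0) ? std::log(lik) + logscale : R_NegInf;
      if (percol) percol[col - c0] = ll;
      total += ll;
    }
    return total;
  }
};

static const double LOG_S_LO = std::log(1e-3);
static const double LOG_S_HI = std::log(100.0);
static const double LOG_RHO_HI = std::log(100.0);
static const double GOLD = 0.3819660112501051;  // 2 - phi

// Brent local minimization of g over [a, b] (Brent 1973, as in optimize());
// tol is an absolute tolerance in x
template <typename F>
static double brent_min(F g, double a, double b, double tol, double* gbest) {
  double x = a + GOLD * (b - a), w = x, v = x, d = 0.0, e = 0.0;
  double fx = g(x), fw = fx, fv = fx;
  for (int it = 0; it < 200; ++it) {
    const double m = 0.5 * (a + b);
    const double t = tol, t2 = 2.0 * t;
    if (std::fabs(x - m) <= t2 - 0.5 * (b - a)) break;
    double p = 0.0, q = 0.0, r = 0.0;
    if (std::fabs(e) > t) {
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p; else q = -q;
      r = e; e = d;
    }
    if (std::fabs(p) < std::fabs(0.5 * q * r) && p > q * (a - x) && p < q * (b - x)) {
      d = p / q;                       // parabolic interpolation step
      const double u = x + d;
      if (u - a < t2 || b - u < t2) d = (x < m) ? t : -t;
    } else {
      e = (x < m) ? b - x : a - x;     // golden-section fallback
      d = GOLD * e;
    }
    const double u = (std::fabs(d) >= t) ? x + d : x + ((d > 0.0) ? t : -t);
    const double fu = g(u);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  *gbest = fx;
  return x;
}

template <typename F>
static double golden_max(F f, double a, double b, double tol, double* fbest) {
  double gb;
  const double x = brent_min([&](double z) { return -f(z); }, a, b, tol, &gb);
  *fbest = -gb;
  return x;
}

struct FitResult {
  double lnL_null, s_null, lnL_alt, s_alt, rho;
};

// constrained fits over columns [c0, c1): null (rho = 1, free s) and
// alternative (free s, rho in [1, 100]); coordinate ascent with golden
// sections on log scale from two starts, nesting enforced
static FitResult fit_chunk(const PruneCtx& ctx, int c0, int c1) {
  FitResult r;
  auto ll_null = [&](double x) { return ctx.loglik_range(std::exp(x), 1.0, c0, c1); };
  double f0;
  double xs = golden_max(ll_null, LOG_S_LO, LOG_S_HI, 1e-7, &f0);
  r.lnL_null = f0;
  r.s_null = std::exp(xs);

  double best_ll = R_NegInf, best_s = r.s_null, best_rho = 1.0;
  const double starts[2] = {0.0, std::log(2.0)};
  for (double rho0 : starts) {
    double lx = xs, rx = rho0;
    double cur = ctx.loglik_range(std::exp(lx), std::exp(rx), c0, c1);
    for (int sweep = 0; sweep < 12; ++sweep) {
      double f1, f2;
      // full-span passes on the first sweep; later sweeps search a narrow
      // bracket around the current optimum, re-expanding if a bound is hit
      double rlo = 0.0, rhi = LOG_RHO_HI, slo = LOG_S_LO, shi = LOG_S_HI;
      if (sweep > 0) {
        rlo = std::max(0.0, rx - 0.75); rhi = std::min(LOG_RHO_HI, rx + 0.75);
        slo = std::max(LOG_S_LO, lx - 0.75); shi = std::min(LOG_S_HI, lx + 0.75);
      }
      auto fr = [&](double x) { return ctx.loglik_range(std::exp(lx), std::exp(x), c0, c1); };
      rx = golden_max(fr, rlo, rhi, 1e-7, &f1);
      if (sweep > 0 && (rx - rlo < 1e-6 || rhi - rx < 1e-6) &&
          !(rx < 1e-6 || LOG_RHO_HI - rx < 1e-6))
        rx = golden_max(fr, 0.0, LOG_RHO_HI, 1e-7, &f1);
      auto fs = [&](double x) { return ctx.loglik_range(std::exp(x), std::exp(rx), c0, c1); };
      lx = golden_max(fs, slo, shi, 1e-7, &f2);
      if (sweep > 0 && (lx - slo < 1e-6 || shi - lx < 1e-6) &&
          !(lx - LOG_S_LO < 1e-6 || LOG_S_HI - lx < 1e-6))
        lx = golden_max(fs, LOG_S_LO, LOG_S_HI, 1e-7, &f2);
      if (f2 - cur < 1e-9) { cur = std::max(cur, f2); break; }
      cur = f2;
    }
    if (cur > best_ll) { best_ll = cur; best_s = std::exp(lx); best_rho = std::exp(rx); }
  }
  // nested null floor; prefer rho = 1 when the improvement is negligible
  if (best_ll < r.lnL_null + 1e-8) {
    best_ll = std::max(best_ll, r.lnL_null);
    best_s = r.s_null;
    best_rho = 1.0;
  }
  r.lnL_alt = best_ll;
  r.s_alt = best_s;
  r.rho = best_rho;
  return r;
}

// [[Rcpp::export]]
List cpp_element_loglik(IntegerVector parent, IntegerVector child,
                        NumericVector len, LogicalVector in_sub,
                        double s, double rho,
                        NumericMatrix U, NumericVector lam,
                        NumericMatrix Uinv, NumericVector pi,
                        int nnode, int root,
                        IntegerMatrix data, IntegerVector tip_node) {
  PruneCtx ctx(parent, child, len, in_sub, U, lam, Uinv, pi, nnode, root,
               data, tip_node);
  NumericVector percol(ctx.L);
  double total = ctx.loglik_range(s, rho, 0, ctx.L,
                                  ctx.L ? percol.begin() : nullptr);
  return List::create(_["total"] = total, _["percol"] = percol);
}

// [[Rcpp::export]]
List cpp_fit_element(IntegerVector parent, IntegerVector child,
                     NumericVector len, LogicalVector in_sub,
                     NumericMatrix U, NumericVector lam,
                     NumericMatrix Uinv, NumericVector pi,
                     int nnode, int root,
                     IntegerMatrix data, IntegerVector tip_node) {
  PruneCtx ctx(parent, child, len, in_sub, U, lam, Uinv, pi, nnode, root,
               data, tip_node);
  FitResult r = fit_chunk(ctx, 0, ctx.L);
  return List::create(_["lnL_null"] = r.lnL_null, _["s_null"] = r.s_null,
                      _["lnL_alt"] = r.lnL_alt, _["s_alt"] = r.s_alt,
                      _["rho"] = r.rho);
}

// LRT statistics for n_sims consecutive simulated elements of length L
// packed column-wise into one alignment matrix
// [[Rcpp::export]]
NumericVector cpp_null_lrts(IntegerVector parent, IntegerVector child,
                            NumericVector len, LogicalVector in_sub,
                            NumericMatrix U, NumericVector lam,
                            NumericMatrix Uinv, NumericVector pi,
                            int nnode, int root,
                            IntegerMatrix data, IntegerVector tip_node,
                            int L, int n_sims) {
  PruneCtx ctx(parent, child, len, in_sub, U, lam, Uinv, pi, nnode, root,
               data, tip_node);
  if ((size_t)L * n_sims != (size_t)ctx.L)
    stop("data has %d columns; expected L * n_sims = %d", ctx.L, L * n_sims);
  NumericVector out(n_sims);
  for (int i = 0; i < n_sims; ++i) {
    FitResult r = fit_chunk(ctx, i * L, (i + 1) * L);
    double lrt = 2.0 * (r.lnL_alt - r.lnL_null);
    out[i] = lrt > 0.0 ? lrt : 0.0;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
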