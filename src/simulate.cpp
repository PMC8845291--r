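#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Synchronous Boolean dynamics with post-update bit-flip noise.
//
// tt:      n x 4 per-rule truth tables, column 1 + b1 + 2*b2 over the bits
//          of the rule's inputs; nin: inputs per rule, 0 flags a frozen
//          constant rule; inputs: n x 2 zero-based input indices.
// A constant (lesion-isolated) rule restores the node's initial state at
// every update, so its activity stays constant over time and a bit-flip on
// it survives exactly one recorded step. Subset flips are applied before
// baseline flips; both act on the freshly updated state, so a perturbed
// node can flip twice in one step. Recorded states are post-flip; the
// first burn_in steps are discarded.
// [[Rcpp::export]]
IntegerMatrix sim_discrete_core(const IntegerMatrix& tt,
                                const IntegerVector& nin,
                                const IntegerMatrix& inputs,
                                const IntegerVector& init,
                                int steps, int burn_in,
                                const LogicalVector& perturbed,
                                double flip_p, double baseline_flip_p) {
  const int n = init.size();
  IntegerMatrix out(steps - burn_in, n);
  std::vector<int> s(init.begin(), init.end()), nxt(n);
  for (int t = 0; t < steps; ++t) {
    for (int i = 0; i < n; ++i) {
      const int m = nin[i];
      if (m == 0) {
        nxt[i] = init[i];
      } else {
        int idx = s[inputs(i, 0)];
        if (m == 2) idx += 2 * s[inputs(i, 1)];
        nxt[i] = tt(i, idx);
      }
    }
    if (flip_p > 0.0) {
      for (int i = 0; i < n; ++i)
        if (perturbed[i] && unif_rand() < flip_p) nxt[i] ^= 1;
    }
    if (baseline_flip_p > 0.0) {
      for (int i = 0; i < n; ++i)
        if (unif_rand() < baseline_flip_p) nxt[i] ^= 1;
    }
    s = nxt;
    if (t >= burn_in)
      for (int i = 0; i < n; ++i) out(t - burn_in, i) = s[i];
  }
  return out;
}

static inline double hill_act(double x, double theta_h, double h) {
  if (x <= 0.0) return 0.0;
  const double xh = std::pow(x, h);
  return xh / (theta_h + xh);
}

// Euler-Maruyama integration of the soft-logic gene expression model.
//
// op: 0 = frozen constant (production term fixed at the Hill activation of
// the gene's initial level), 1 = single regulator, 2 = AND, 3 = OR; neg
// applies NOT to the corresponding Hill-activated leaf (AND with a negated
// second leaf realizes "A AND NOT B"; OR is the probabilistic sum).
// Perturbed genes receive additive N(0, pert_sd) noise each recorded step;
// states are clamped at zero from below.
// [[Rcpp::export]]
NumericMatrix sim_sde_core(const IntegerVector& op,
                           const IntegerMatrix& inputs,
                           const LogicalMatrix& neg,
                           const NumericVector& x0,
                           double prod_rate, double degr_rate,
                           double theta, double hill,
                           double sigma_sys, double dt,
                           int steps, int burn_in,
                           const LogicalVector& perturbed, double pert_sd) {
  const int n = x0.size();
  NumericMatrix out(steps - burn_in, n);
  std::vector<double> x(x0.begin(), x0.end()), drift(n), rconst(n);
  const double theta_h = std::pow(theta, hill);
  const double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i)
    if (op[i] == 0) rconst[i] = hill_act(x0[i], theta_h, hill);
  for (int t = 0; t < steps; ++t) {
    for (int i = 0; i < n; ++i) {
      double r;
      if (op[i] == 0) {
        r = rconst[i];
      } else {
        double a = hill_act(x[inputs(i, 0)], theta_h, hill);
        if (neg(i, 0)) a = 1.0 - a;
        if (op[i] == 1) {
          r = a;
        } else {
          double b = hill_act(x[inputs(i, 1)], theta_h, hill);
          if (neg(i, 1)) b = 1.0 - b;
          r = (op[i] == 2) ? a * b : a + b - a * b;
        }
      }
      drift[i] = prod_rate * r - degr_rate * x[i];
    }
    for (int i = 0; i < n; ++i) {
      double xi = x[i] + dt * drift[i];
      if (sigma_sys > 0.0) xi += sigma_sys * sdt * norm_rand();
      if (perturbed[i] && pert_sd > 0.0) xi += pert_sd * norm_rand();
      if (xi < 0.0) xi = 0.0;
      if (!std::isfinite(xi))
        stop("integration failure: non-finite state at step %d", t + 1);
      x[i] = xi;
    }
    if (t >= burn_in)
      for (int i = 0; i < n; ++i) out(t - burn_in, i) = x[i];
  }
  return out;
}
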