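// L0-penalized least squares on the Gram scale.
//
// Minimizes  (z'z - 2 b'beta + beta' G beta)/N + lambda * ||beta||_0
// where G = X'X and b = X'z are computed on centered variables, so the
// intercept is profiled out. Coordinate descent followed by a local search
// over support moves (add / drop / swap). Moves are scored exactly with
// joint-OLS objectives via rank-one update identities: the gain of adding
// variable l to support S is r_l^2 / d_l with r_l the partial residual
// correlation and d_l the residual variance of x_l after projecting on S;
// dropping j costs beta_j^2 / [ (G_SS)^-1 ]_jj; swaps combine a drop
// (inverse downdate) with the best add on the reduced support.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double EPS_GAIN = 1e-12;
static const double EPS_DIAG = 1e-10;

static void cd_sweeps(const arma::mat& G, const arma::vec& b, double N,
                      double lambda, arma::vec& beta, arma::vec& gb,
                      int max_sweeps, double tol) {
  const arma::uword k = G.n_rows;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double maxchg = 0.0;
    for (arma::uword j = 0; j < k; ++j) {
      const double gjj = G(j, j);
      const double old = beta(j);
      double nb = 0.0;
      if (gjj > EPS_DIAG) {
        const double rj = b(j) - gb(j) + gjj * old;
        const double bols = rj / gjj;
        if (bols * bols * gjj / N > lambda) nb = bols;
      }
      if (nb != old) {
        const double d = nb - old;
        gb += G.col(j) * d;
        beta(j) = nb;
        double a = std::fabs(d);
        if (a > maxchg) maxchg = a;
      }
    }
    if (maxchg < tol) break;
  }
}

// Best addition to a support whose inverse Gram (inv), OLS coefficients (u)
// and RSS are given. Fills gain and index; returns true if any candidate.
static bool best_add(const arma::mat& G, const arma::vec& b,
                     const arma::uvec& S, const arma::mat& inv,
                     const arma::vec& u, const arma::vec& active_mask,
                     double& gain, arma::sword& idx) {
  const arma::uword k = G.n_rows;
  gain = 0.0; idx = -1;
  if (S.n_elem == 0) {
    for (arma::uword l = 0; l < k; ++l) {
      if (active_mask(l) != 0.0 || G(l, l) <= EPS_DIAG) continue;
      double g = b(l) * b(l) / G(l, l);
      if (g > gain) { gain = g; idx = l; }
    }
    return idx >= 0;
  }
  // W = inv * G(S, :) ; r = b - G(:,S) u ; d_l = g_ll - G(l,S) W(:,l)
  arma::mat GS = G.rows(S);          // |S| x k
  arma::mat W = inv * GS;            // |S| x k
  arma::vec r = b - GS.t() * u;      // k
  arma::rowvec dcorr = arma::sum(GS % W, 0);  // k
  for (arma::uword l = 0; l < k; ++l) {
    if (active_mask(l) != 0.0 || G(l, l) <= EPS_DIAG) continue;
    double d = G(l, l) - dcorr(l);
    if (d <= EPS_DIAG) continue;
    double g = r(l) * r(l) / d;
    if (g > gain) { gain = g; idx = l; }
  }
  return idx >= 0;
}

// One round of support moves; returns true if an improving move was applied.
static bool improve_support(const arma::mat& G, const arma::vec& b,
                            double ztz, double N, double lambda,
                            arma::vec& beta, arma::vec& gb,
                            arma::uword max_swap_support) {
  const arma::uword k = G.n_rows;
  arma::uvec S = arma::find(beta != 0.0);
  const arma::uword s = S.n_elem;

  arma::mat inv;
  arma::vec u;
  double rss;
  if (s > 0) {
    arma::mat GSS = G.submat(S, S);
    if (!arma::inv_sympd(inv, GSS)) {
      if (!arma::pinv(inv, GSS)) return false;
    }
    u = inv * b.elem(S);
    rss = ztz - arma::dot(b.elem(S), u);
  } else {
    rss = ztz;
  }
  const double cur = rss / N + lambda * s;

  double best_obj = cur;
  int move = 0;                 // 1 = add, 2 = drop, 3 = swap
  arma::sword add_idx = -1, drop_pos = -1, swap_pos = -1, swap_idx = -1;

  arma::vec mask(k, arma::fill::zeros);
  mask.elem(S).ones();

  double gain; arma::sword idx;
  if (best_add(G, b, S, inv, u, mask, gain, idx)) {
    double obj = (rss - gain) / N + lambda * (s + 1);
    if (obj < best_obj - EPS_GAIN) { best_obj = obj; move = 1; add_idx = idx; }
  }
  for (arma::uword a = 0; a < s; ++a) {
    if (inv(a, a) <= EPS_DIAG) continue;
    double inc = u(a) * u(a) / inv(a, a);
    double obj = (rss + inc) / N + lambda * (s - 1);
    if (obj < best_obj - EPS_GAIN) { best_obj = obj; move = 2; drop_pos = a; }
  }
  if (s > 0 && s <= max_swap_support) {
    for (arma::uword a = 0; a < s; ++a) {
      if (inv(a, a) <= EPS_DIAG) continue;
      arma::uvec keep = arma::regspace<arma::uvec>(0, s - 1);
      keep.shed_row(a);
      arma::uvec S2 = S.elem(keep);
      // downdated inverse of G(S2,S2)
      arma::mat inv2 = inv.submat(keep, keep)
        - inv.submat(keep, arma::uvec{a}) * inv.submat(arma::uvec{a}, keep)
          / inv(a, a);
      arma::vec u2 = inv2 * b.elem(S2);
      double rss2 = ztz - arma::dot(b.elem(S2), u2);
      arma::vec mask2 = mask;
      mask2(S(a)) = 0.0;
      if (best_add(G, b, S2, inv2, u2, mask2, gain, idx)) {
        double obj = (rss2 - gain) / N + lambda * s;
        if (obj < best_obj - EPS_GAIN) {
          best_obj = obj; move = 3; swap_pos = a; swap_idx = idx;
        }
      }
    }
  }

  if (move == 0) {
    // settle on the joint OLS solution of the current support
    if (s > 0) {
      beta.zeros();
      beta.elem(S) = u;
      gb = G * beta;
    }
    return false;
  }
  arma::uvec Snew;
  if (move == 1) {
    Snew = arma::join_cols(S, arma::uvec{(arma::uword) add_idx});
  } else if (move == 2) {
    Snew = S; Snew.shed_row(drop_pos);
  } else {
    Snew = S; Snew.shed_row(swap_pos);
    Snew = arma::join_cols(Snew, arma::uvec{(arma::uword) swap_idx});
  }
  beta.zeros();
  if (Snew.n_elem) {
    arma::vec coef;
    if (!arma::solve(coef, G.submat(Snew, Snew), b.elem(Snew),
                     arma::solve_opts::no_approx)) return false;
    beta.elem(Snew) = coef;
  }
  gb = G * beta;
  return true;
}

static double objective_of(const arma::mat& G, const arma::vec& b,
                           double ztz, double N, double lambda,
                           const arma::vec& beta, const arma::vec& gb) {
  double rss = ztz - 2.0 * arma::dot(b, beta) + arma::dot(beta, gb);
  int nnz = 0;
  for (arma::uword j = 0; j < beta.n_elem; ++j) if (beta(j) != 0.0) ++nnz;
  return rss / N + lambda * nnz;
}

//' @noRd
// [[Rcpp::export(name = ".l0_cd_path")]]
Rcpp::List l0_cd_path(const arma::mat& G, const arma::vec& b, double ztz,
                      double N, const arma::vec& lambdas,
                      int max_sweeps = 100, double tol = 1e-8,
                      int search_rounds = 50, int max_swap_support = 30,
                      int max_supp = 100, int max_search = 40) {
  const arma::uword k = G.n_rows;
  const arma::uword nl = lambdas.n_elem;
  arma::mat betas(k, nl, arma::fill::zeros);
  arma::vec objs(nl);
  arma::vec beta(k, arma::fill::zeros);
  arma::vec gb(k, arma::fill::zeros);
  for (arma::uword t = 0; t < nl; ++t) {
    const double lambda = lambdas(t);
    cd_sweeps(G, b, N, lambda, beta, gb, max_sweeps, tol);
    // The move search refines small and moderate supports (where the
    // CV-selected model lives); deep-overfit path segments keep the plain
    // coordinate-descent solution.
    if (arma::uword(arma::accu(beta != 0.0)) <= arma::uword(max_search)) {
      for (int r = 0; r < search_rounds; ++r) {
        if (!improve_support(G, b, ztz, N, lambda, beta, gb,
                             (arma::uword) max_swap_support)) break;
        cd_sweeps(G, b, N, lambda, beta, gb, max_sweeps, tol);
      }
    }
    betas.col(t) = beta;
    objs(t) = objective_of(G, b, ztz, N, lambda, beta, gb);
    // Path termination at a support-size cap, as best-subset path solvers
    // do: smaller lambdas would only grow the support further; reuse the
    // current solution for the remaining grid points.
    if (arma::uword(arma::accu(beta != 0.0)) > arma::uword(max_supp)) {
      for (arma::uword t2 = t + 1; t2 < nl; ++t2) {
        betas.col(t2) = beta;
        objs(t2) = objective_of(G, b, ztz, N, lambdas(t2), beta, gb);
      }
      break;
    }
  }
  return Rcpp::List::create(Rcpp::Named("beta") = betas,
                            Rcpp::Named("objective") = objs);
}
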