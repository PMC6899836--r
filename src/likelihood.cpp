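// Compiled inner loops of the aggregated bid likelihood.
//
// Trials arrive stacked subject-by-subject, market-by-market, in
// chronological order; `newseq` marks the first trial of each
// subject-market sequence, where the agent's state is reset. The grid is
// 0.0..10.0 in 0.1 steps (101 points). Per-trial log-probabilities below
// -745 are floored (degenerate scales must not yield -Inf objectives);
// the number of floored trials is returned alongside the per-subject
// totals.
//
// Laplace-side normalization constants over the grid are geometric series
// and are summed in closed form; Gaussian weights are summed explicitly.

#include <Rcpp.h>
using namespace Rcpp;

static const double FLOOR = -745.0;
static const int NG = 101;

static inline double grid_val(int j) { return j / 10.0; } // j = 0..100

// number of grid points strictly below a (continuous) preferred bid
static inline int n_below(double A) {
  int nb = (int)std::ceil(A * 10.0 - 1e-9);
  if (nb < 0) nb = 0;
  if (nb > NG) nb = NG;
  return nb;
}

// sum of exp(-d/s) over count points starting at distance d0, step 0.1
static inline double lap_side_sum(double d0, int count, double s) {
  if (count <= 0) return 0.0;
  double r = std::exp(-0.1 / s);
  double first = std::exp(-d0 / s);
  if (r > 1.0 - 1e-12) return first * count; // s huge: ratio ~ 1
  return first * (1.0 - std::pow(r, count)) / (1.0 - r);
}

// model ids: 1 dl_gauss, 2 dl_naive, 3 dl_lepto
// last: 0 none, 1 accepted, 2 rejected
// [[Rcpp::export]]
List cpp_dl_nll(int model, NumericVector params,
                IntegerVector subj, IntegerVector market,
                NumericVector bid, IntegerVector bididx,
                IntegerVector accepted, NumericVector reward,
                LogicalVector newseq, NumericVector A0,
                int n_subj) {
  int n = subj.size();
  NumericVector out(n_subj);
  NumericVector A_pre(n);
  IntegerVector last_pre(n);
  int nfloor = 0;
  double A[3] = {0, 0, 0};
  int last[3] = {0, 0, 0};

  double alpha = 0, sigma = 0, n_up = 0, n_down = 0;
  double sigma_a = 0, sigma_r = 0, sigma_0 = 0, k = 0;
  if (model == 1) { alpha = params[0]; sigma = params[1]; }
  else if (model == 2) {
    n_up = params[0]; n_down = params[1];
    sigma_a = params[2]; sigma_r = params[3];
  } else {
    alpha = params[0]; sigma_a = params[1]; sigma_r = params[2];
    sigma_0 = params[3]; k = params[4];
  }

  for (int i = 0; i < n; ++i) {
    int m = market[i] - 1;
    if (newseq[i]) { A[m] = A0[m]; last[m] = 0; }
    double a = A[m];
    A_pre[i] = a;
    last_pre[i] = last[m];
    double ll;

    if (model == 1) { // Gaussian jitter around the preferred bid
      double s2 = 2.0 * sigma * sigma, sum = 0.0;
      for (int j = 0; j < NG; ++j) {
        double d = grid_val(j) - a;
        sum += std::exp(-d * d / s2);
      }
      double d = bid[i] - a;
      ll = -d * d / s2 - std::log(sum);
    } else {
      // side scales by previous outcome
      double sb, su, kk = 0.5;
      if (model == 2) {
        sb = (last[m] == 0) ? 0.5 * (sigma_a + sigma_r) : sigma_a;
        su = (last[m] == 0) ? 0.5 * (sigma_a + sigma_r) : sigma_r;
      } else {
        sb = (last[m] == 1) ? sigma_a : sigma_0;
        su = (last[m] == 2) ? sigma_r : sigma_0;
        kk = (last[m] == 0) ? 0.5 : k;
      }
      int nb = n_below(a);
      double d0b = a - grid_val(nb - 1);            // nearest below distance
      double d0a = grid_val(nb) - a;                // nearest at-or-above
      double sum_b = lap_side_sum(d0b, nb, sb);
      double sum_a = lap_side_sum(d0a, NG - nb, su);
      bool chosen_below = bid[i] < a;
      double d = std::fabs(bid[i] - a);
      if (model == 2) {
        // density prefactors 1/(2s) weight the two sides against each other
        double tot = sum_b / (2.0 * sb) + sum_a / (2.0 * su);
        double w = std::exp(-d / (chosen_below ? sb : su)) /
          (2.0 * (chosen_below ? sb : su));
        ll = std::log(w / tot);
      } else {
        if (nb == 0) kk = 0.0;                      // no strictly-below bids
        double w, sidesum, mass;
        if (chosen_below) { w = std::exp(-d / sb); sidesum = sum_b; mass = kk; }
        else { w = std::exp(-d / su); sidesum = sum_a; mass = 1.0 - kk; }
        ll = std::log(mass * w / sidesum);
      }
    }

    if (!std::isfinite(ll) || ll < FLOOR) { ll = FLOOR; ++nfloor; }
    out[subj[i] - 1] -= ll;

    // learning update
    if (model == 2) {
      A[m] += accepted[i] ? -n_up : n_down;
    } else {
      if (accepted[i]) {
        double step = bid[i] - a;                   // accept: stay or follow down
        if (step < 0) A[m] += alpha * step;
      } else {
        A[m] += alpha * (10.0 - a);                 // reject: push toward 10
      }
    }
    if (A[m] < 0) A[m] = 0;
    if (A[m] > 10) A[m] = 10;
    last[m] = accepted[i] ? 1 : 2;
  }
  return List::create(_["nll"] = out, _["nfloor"] = nfloor,
                      _["A_pre"] = A_pre, _["last_pre"] = last_pre);
}

// model ids: 1 rw_coarse, 2 rw_fine, 3 counterfactual_rl
// Q0: (3 markets) x (nbins) initial action values; tiles: bin of each grid
// point (1-based, rw_coarse only); sizes: grid points per bin
// [[Rcpp::export]]
List cpp_rl_nll(int model, NumericVector params,
                IntegerVector subj, IntegerVector market,
                NumericVector bid, IntegerVector bididx,
                IntegerVector accepted, NumericVector reward,
                LogicalVector newseq, NumericMatrix Q0,
                IntegerVector tiles, IntegerVector sizes,
                int n_subj) {
  int n = subj.size();
  int nbins = Q0.ncol();
  NumericVector out(n_subj);
  int nfloor = 0;
  double alpha = params[0], beta = params[1];
  std::vector<double> Q(3 * nbins, 0.0);

  for (int i = 0; i < n; ++i) {
    int m = market[i] - 1;
    double* q = &Q[m * nbins];
    if (newseq[i]) for (int j = 0; j < nbins; ++j) q[j] = Q0(m, j);

    double mx = q[0];
    for (int j = 1; j < nbins; ++j) if (q[j] > mx) mx = q[j];
    double sum = 0.0;
    for (int j = 0; j < nbins; ++j) sum += std::exp(beta * (q[j] - mx));
    double lse = beta * mx + std::log(sum);

    int gi = bididx[i] - 1;                          // 0-based grid index
    double ll;
    if (model == 1) {
      int b = tiles[gi] - 1;
      ll = beta * q[b] - lse - std::log((double)sizes[b]);
      q[b] += alpha * (reward[i] - q[b]);
    } else if (model == 2) {
      ll = beta * q[gi] - lse;
      q[gi] += alpha * (reward[i] - q[gi]);
    } else {
      ll = beta * q[gi] - lse;
      if (accepted[i]) {
        for (int j = gi; j < nbins; ++j)             // i >= b: toward 10 - i
          q[j] += alpha * ((10.0 - grid_val(j)) - q[j]);
      } else {
        for (int j = 0; j <= gi; ++j)                // i <= b: toward 0
          q[j] += alpha * (0.0 - q[j]);
      }
    }
    if (!std::isfinite(ll) || ll < FLOOR) { ll = FLOOR; ++nfloor; }
    out[subj[i] - 1] -= ll;
  }
  return List::create(_["nll"] = out, _["nfloor"] = nfloor);
}
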