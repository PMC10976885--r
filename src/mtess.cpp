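// Compiled cores: the evolutionary stochastic search sampler over model
// indicators, exact enumeration of small model spaces, and the blockwise
// coordinate-descent graphical lasso used inside stability selection.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int rand_below(int n) {
  // uniform integer in [0, n), driven by R's RNG so set.seed() governs
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// Log marginal likelihood (up to a gamma-independent constant) of the
// multivariate-response g-prior model, from precomputed cross-products:
//   -(q k / 2) log(1+g) - (nu/2) logdet(Y'Y - g/(1+g) H_g' G_gg^{-1} H_g)
// Returns -Inf when G_gg is numerically rank deficient (auto-reject).
static double log_marginal_idx(const arma::mat& G, const arma::mat& H,
                               const arma::mat& YtY, const arma::uvec& idx,
                               double nu, double g, double log1g) {
  const double q = (double)YtY.n_rows;
  const int k = idx.n_elem;
  arma::mat M = YtY;
  if (k > 0) {
    arma::mat Ggg = G.submat(idx, idx);
    arma::mat Hg = H.rows(idx);
    arma::mat R;
    if (!arma::chol(R, Ggg)) return -arma::datum::inf;
    arma::mat Z = arma::solve(arma::trimatl(R.t()), Hg);
    M -= (g / (1.0 + g)) * (Z.t() * Z);
  }
  double ldet, sign;
  if (!arma::log_det(ldet, sign, M) || sign <= 0.0) return -arma::datum::inf;
  return -0.5 * q * k * log1g - 0.5 * nu * ldet;
}

struct ChainState {
  std::vector<int> gam; // 0/1 inclusion
  int k;
  double lp; // log posterior (marginal + size prior), untempered
};

static arma::uvec gam_to_idx(const std::vector<int>& gam) {
  std::vector<arma::uword> v;
  for (size_t j = 0; j < gam.size(); ++j) if (gam[j]) v.push_back(j);
  return arma::uvec(v);
}

// [[Rcpp::export(name = ".guess_sampler_cpp")]]
List guess_sampler_cpp(const arma::mat& G, const arma::mat& H,
                       const arma::mat& YtY, double nu, double g,
                       const arma::vec& log_model_prior, int Tmax,
                       int n_sweeps, int burn_in, int n_chains,
                       double temp_ratio, double prob_crossover,
                       bool adapt_temps) {
  const int p = G.n_rows;
  const double log1g = std::log1p(g);

  auto logpost = [&](const std::vector<int>& gam, int k) -> double {
    if (k > Tmax) return -arma::datum::inf;
    double prior = log_model_prior[k];
    if (!std::isfinite(prior)) return -arma::datum::inf;
    return log_marginal_idx(G, H, YtY, gam_to_idx(gam), nu, g, log1g) + prior;
  };

  // chains start empty (the null model is always in support)
  std::vector<ChainState> ch(n_chains);
  std::vector<int> empty_gam(p, 0);
  double lp0 = logpost(empty_gam, 0);
  for (int c = 0; c < n_chains; ++c) ch[c] = ChainState{empty_gam, 0, lp0};

  std::vector<double> temps(n_chains);
  double ratio = temp_ratio;
  auto set_temps = [&]() {
    for (int c = 0; c < n_chains; ++c) temps[c] = std::pow(ratio, c);
  };
  set_temps();

  IntegerVector trace_size(n_sweeps);
  NumericVector trace_lp(n_sweeps);
  int n_keep = n_sweeps - burn_in;
  IntegerMatrix cold(n_keep, p);

  long ex_att = 0, ex_acc = 0;         // post burn-in exchange stats
  long ad_att = 0, ad_acc = 0;         // adaptation window stats
  const int adapt_every = 100;
  long mut_att = 0, mut_acc = 0;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    // --- mutation move per chain: add 0.45 / delete 0.45 / swap 0.10 ---
    for (int c = 0; c < n_chains; ++c) {
      double u = unif_rand();
      std::vector<int> prop = ch[c].gam;
      int kn = ch[c].k;
      double log_qratio = 0.0; // log q(rev)/q(fwd)
      bool ok = true;
      if (u < 0.45) { // add
        if (ch[c].k >= p || ch[c].k >= Tmax) ok = false;
        else {
          int pick = rand_below(p - ch[c].k), seen = 0, j = -1;
          for (int m = 0; m < p; ++m) if (!prop[m] && seen++ == pick) { j = m; break; }
          prop[j] = 1; kn = ch[c].k + 1;
          log_qratio = std::log((double)(p - ch[c].k) / (double)kn);
        }
      } else if (u < 0.90) { // delete
        if (ch[c].k == 0) ok = false;
        else {
          int pick = rand_below(ch[c].k), seen = 0, j = -1;
          for (int m = 0; m < p; ++m) if (prop[m] && seen++ == pick) { j = m; break; }
          prop[j] = 0; kn = ch[c].k - 1;
          log_qratio = std::log((double)ch[c].k / (double)(p - kn));
        }
      } else { // swap (symmetric)
        if (ch[c].k == 0 || ch[c].k == p) ok = false;
        else {
          int pi = rand_below(ch[c].k), po = rand_below(p - ch[c].k);
          int seen = 0, jin = -1, jout = -1;
          for (int m = 0; m < p; ++m) if (prop[m] && seen++ == pi) { jin = m; break; }
          seen = 0;
          for (int m = 0; m < p; ++m) if (!prop[m] && seen++ == po) { jout = m; break; }
          prop[jin] = 0; prop[jout] = 1;
        }
      }
      if (ok) {
        mut_att++;
        double lp_new = logpost(prop, kn);
        double la = (lp_new - ch[c].lp) / temps[c] + log_qratio;
        if (std::isfinite(lp_new) && std::log(unif_rand()) < la) {
          ch[c].gam = prop; ch[c].k = kn; ch[c].lp = lp_new; mut_acc++;
        }
      }
    }

    // --- crossover between two random chains (uniform crossover) ---
    if (n_chains >= 2 && unif_rand() < prob_crossover) {
      int a = rand_below(n_chains);
      int b = rand_below(n_chains - 1);
      if (b >= a) b++;
      std::vector<int> ca = ch[a].gam, cb = ch[b].gam;
      for (int m = 0; m < p; ++m)
        if (ch[a].gam[m] != ch[b].gam[m] && unif_rand() < 0.5)
          std::swap(ca[m], cb[m]);
      int ka = 0, kb = 0;
      for (int m = 0; m < p; ++m) { ka += ca[m]; kb += cb[m]; }
      double lpa = logpost(ca, ka), lpb = logpost(cb, kb);
      if (std::isfinite(lpa) && std::isfinite(lpb)) {
        double la = (lpa - ch[a].lp) / temps[a] + (lpb - ch[b].lp) / temps[b];
        if (std::log(unif_rand()) < la) {
          ch[a].gam = ca; ch[a].k = ka; ch[a].lp = lpa;
          ch[b].gam = cb; ch[b].k = kb; ch[b].lp = lpb;
        }
      }
    }

    // --- exchange between a random adjacent-temperature pair ---
    if (n_chains >= 2) {
      int m = rand_below(n_chains - 1);
      double la = (1.0 / temps[m] - 1.0 / temps[m + 1]) * (ch[m + 1].lp - ch[m].lp);
      bool acc = std::log(unif_rand()) < la;
      if (acc) std::swap(ch[m], ch[m + 1]);
      ad_att++; ad_acc += acc;
      if (sweep >= burn_in) { ex_att++; ex_acc += acc; }
    }

    // --- temperature-ladder adaptation during burn-in ---
    if (adapt_temps && n_chains >= 2 && sweep < burn_in &&
        (sweep + 1) % adapt_every == 0 && ad_att > 0) {
      double acc_rate = (double)ad_acc / (double)ad_att;
      // spread the ladder when exchanges are too easy, tighten when too hard
      ratio = 1.0 + (ratio - 1.0) * std::exp(0.5 * (acc_rate - 0.5));
      if (ratio < 1.001) ratio = 1.001;
      if (ratio > 8.0) ratio = 8.0;
      set_temps();
      ad_att = 0; ad_acc = 0;
    }

    trace_size[sweep] = ch[0].k;
    trace_lp[sweep] = ch[0].lp;
    if (sweep >= burn_in)
      for (int m = 0; m < p; ++m) cold(sweep - burn_in, m) = ch[0].gam[m];
  }

  return List::create(
    _["cold_states"] = cold,
    _["trace_size"] = trace_size,
    _["trace_logpost"] = trace_lp,
    _["temperatures"] = NumericVector(temps.begin(), temps.end()),
    _["exchange_rate"] = ex_att > 0 ? (double)ex_acc / ex_att : NA_REAL,
    _["mutation_rate"] = mut_att > 0 ? (double)mut_acc / mut_att : NA_REAL);
}

// [[Rcpp::export(name = ".guess_enumerate_cpp")]]
NumericVector guess_enumerate_cpp(const arma::mat& G, const arma::mat& H,
                                  const arma::mat& YtY, double nu, double g,
                                  const arma::vec& log_model_prior, int Tmax) {
  const int p = G.n_rows;
  if (p > 20) stop("enumeration limited to p <= 20");
  const double log1g = std::log1p(g);
  const int nmod = 1 << p;
  NumericVector out(nmod);
  for (int msk = 0; msk < nmod; ++msk) {
    int k = 0;
    std::vector<arma::uword> v;
    for (int j = 0; j < p; ++j) if (msk & (1 << j)) { v.push_back(j); k++; }
    if (k > Tmax || !std::isfinite(log_model_prior[k])) {
      out[msk] = -arma::datum::inf;
      continue;
    }
    arma::uvec idx(v);
    out[msk] = log_marginal_idx(G, H, YtY, idx, nu, g, log1g) + log_model_prior[k];
  }
  return out;
}

// [[Rcpp::export(name = ".log_marginal_cpp")]]
double log_marginal_cpp(const arma::mat& G, const arma::mat& H,
                        const arma::mat& YtY, const arma::uvec& idx0,
                        double nu, double g) {
  arma::uvec idx = idx0; // 0-based indices of included predictors
  return log_marginal_idx(G, H, YtY, idx, nu, g, std::log1p(g));
}

// Blockwise coordinate-descent graphical lasso (penalised Gaussian
// log-likelihood) with an entrywise penalty matrix. Returns the precision
// matrix estimate.
// [[Rcpp::export(name = ".glasso_cpp")]]
arma::mat glasso_cpp(const arma::mat& S, const arma::mat& Rho,
                     double tol = 1e-4, int maxit = 100) {
  const int p = S.n_rows;
  arma::mat W = S;
  W.diag() += Rho.diag();
  arma::mat B(p - 1 > 0 ? p - 1 : 1, p, arma::fill::zeros); // lasso coefs per column
  if (p == 1) {
    arma::mat Th(1, 1);
    Th(0, 0) = 1.0 / W(0, 0);
    return Th;
  }
  const double thr = tol * arma::mean(arma::mean(arma::abs(S - arma::diagmat(S.diag())))) + 1e-12;

  for (int it = 0; it < maxit; ++it) {
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      arma::uvec idx(p - 1);
      int t = 0;
      for (int m = 0; m < p; ++m) if (m != j) idx[t++] = m;
      arma::mat W11 = W.submat(idx, idx);
      arma::vec s12 = S.col(j);
      s12.shed_row(j);
      arma::vec r12 = Rho.col(j);
      r12.shed_row(j);
      arma::vec beta = B.col(j);
      // inner lasso coordinate descent
      for (int in_it = 0; in_it < 200; ++in_it) {
        double dmax = 0.0;
        for (int i = 0; i < p - 1; ++i) {
          double x = s12[i] - arma::dot(W11.row(i).t(), beta) + W11(i, i) * beta[i];
          double bi = 0.0;
          if (x > r12[i]) bi = (x - r12[i]) / W11(i, i);
          else if (x < -r12[i]) bi = (x + r12[i]) / W11(i, i);
          double d = std::abs(bi - beta[i]);
          if (d > dmax) dmax = d;
          beta[i] = bi;
        }
        if (dmax < 1e-6) break;
      }
      B.col(j) = beta;
      arma::vec w12 = W11 * beta;
      for (int i = 0; i < p - 1; ++i) {
        double d = std::abs(W(idx[i], j) - w12[i]);
        if (d > max_delta) max_delta = d;
        W(idx[i], j) = w12[i];
        W(j, idx[i]) = w12[i];
      }
    }
    if (max_delta < thr) break;
  }

  // recover precision matrix from (W, B)
  arma::mat Theta(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    arma::uvec idx(p - 1);
    int t = 0;
    for (int m = 0; m < p; ++m) if (m != j) idx[t++] = m;
    arma::vec beta = B.col(j);
    double denom = W(j, j) - arma::dot(W.submat(idx, arma::uvec{(arma::uword)j}), beta);
    double tjj = 1.0 / denom;
    Theta(j, j) = tjj;
    for (int i = 0; i < p - 1; ++i) Theta(idx[i], j) = -beta[i] * tjj;
  }
  return 0.5 * (Theta + Theta.t());
}
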