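// Metropolis-within-Gibbs sampler for the Bayesian sparse linear mixed model
//
//   y = X beta + u + e,   beta_i ~ pi N(0, sigma_a^2/tau) + (1-pi) delta_0,
//   u ~ N(0, sigma_b^2/tau K),  K = X X'/p  on column-standardized X.
//
// The sampler works in the eigenbasis of K (inputs UtX = U'X, Uty = U'y,
// d = eigenvalues).  For a given inclusion set G the sparse effects, the
// polygenic term and the residual precision tau are integrated out
// analytically, so the chain moves only over (h, rho, log10 pi, G).
// Hyperparameters map to variance components as
//   sigma_b^2 = h (1-rho) / (1-h),   sigma_a^2 = h rho / ((1-h) pi p).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Deterministic uniforms from a raw 64-bit stream; avoids the
// implementation-defined behaviour of std::uniform_real_distribution.
struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  // integer in [0, n)
  uword unif_int(uword n) { return static_cast<uword>(unif() * n) % n; }
};

double reflect(double x, double lo, double hi) {
  double w = hi - lo;
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
    (void)w;
  }
  return x;
}

struct LikState {
  double loglik;     // integrated log-likelihood (up to a constant)
  vec beta_hat;      // E[beta_G | y, G, h, rho]  (length m)
  vec hinv;          // 1/(1 + sigma_b^2 d_i)
  double quad;       // y' Sigma^{-1} y
  bool ok;
};

// Integrated log-likelihood for hyperparameters + inclusion set.
LikState eval_lik(const mat& UtX, const vec& Uty, const vec& d,
                  const uvec& idx, double h, double rho, double pi_val) {
  LikState st;
  st.ok = true;
  const uword n = Uty.n_elem;
  const uword p = UtX.n_cols;
  const uword m = idx.n_elem;
  const double sb2 = h * (1.0 - rho) / (1.0 - h);
  st.hinv = 1.0 / (1.0 + sb2 * d);
  const double logdetH = -accu(log(st.hinv));
  const double yHy = accu(square(Uty) % st.hinv);

  if (m == 0) {
    st.quad = yHy;
    st.loglik = -0.5 * logdetH - 0.5 * double(n) * std::log(yHy);
    return st;
  }
  const double sa2 = h * rho / ((1.0 - h) * pi_val * double(p));
  mat Xg = UtX.cols(idx);
  mat Xh = Xg.each_col() % st.hinv;            // H^{-1} Xg
  mat M = Xg.t() * Xh;                          // Xg' H^{-1} Xg
  M.diag() += 1.0 / sa2;
  vec v = Xh.t() * Uty;                         // Xg' H^{-1} y
  mat R;
  if (!chol(R, M)) { st.ok = false; st.loglik = -datum::inf; return st; }
  const double logdetM = 2.0 * accu(log(R.diag()));
  vec z = solve(trimatl(R.t()), v);
  st.beta_hat = solve(trimatu(R), z);
  st.quad = yHy - dot(z, z);
  if (st.quad <= 0) { st.ok = false; st.loglik = -datum::inf; return st; }
  st.loglik = -0.5 * (logdetH + double(m) * std::log(sa2) + logdetM)
              - 0.5 * double(n) * std::log(st.quad);
  return st;
}

double log_gamma_prior(uword m, uword p, double pi_val) {
  return double(m) * std::log(pi_val) +
         double(p - m) * std::log(1.0 - pi_val);
}

// Probabilities of picking add/remove/swap given the current set size;
// illegal moves get weight zero and the rest renormalize.
void move_probs(uword m, uword p, int s_max, double& pa, double& pr,
                double& ps) {
  double wa = (m < p && static_cast<int>(m) < s_max) ? 0.4 : 0.0;
  double wr = (m > 0) ? 0.4 : 0.0;
  double ws = (m > 0 && m < p) ? 0.2 : 0.0;
  double tot = wa + wr + ws;
  if (tot == 0.0) { pa = pr = ps = 0.0; return; }
  pa = wa / tot; pr = wr / tot; ps = ws / tot;
}

} // namespace

// [[Rcpp::export(name = ".bslmm_mcmc")]]
Rcpp::List bslmm_mcmc(const arma::mat& UtX, const arma::vec& Uty,
                      const arma::vec& d,
                      int n_steps, int n_burn, int thin,
                      double log10pi_min, double log10pi_max,
                      double fix_rho, int s_max,
                      double step_h, double step_rho, double step_pi,
                      double seed) {
  const uword n = Uty.n_elem;
  const uword p = UtX.n_cols;
  Rng rng(static_cast<uint64_t>(seed));

  const double h_lo = 1e-4, h_hi = 1.0 - 1e-4;
  const bool rho_fixed = fix_rho >= 0.0;
  const bool sparse_on = !(rho_fixed && fix_rho == 0.0);

  double h = 0.5;
  double rho = rho_fixed ? fix_rho : 0.5;
  double l10pi = 0.5 * (log10pi_min + log10pi_max);
  std::vector<uword> incl;                 // current inclusion set
  std::vector<char> in_set(p, 0);

  auto idx_vec = [&]() { return uvec(incl); };
  LikState cur = eval_lik(UtX, Uty, d, idx_vec(), h, rho, std::pow(10.0, l10pi));
  double cur_prior = log_gamma_prior(incl.size(), p, std::pow(10.0, l10pi));

  const int n_out = (n_steps - n_burn + thin - 1) / thin;
  vec ch_h(n_out, fill::zeros), ch_rho(n_out, fill::zeros),
      ch_pi(n_out, fill::zeros);
  ivec ch_m(n_out, fill::zeros);
  vec pip(p, fill::zeros), beta_acc(p, fill::zeros), alpha_acc(p, fill::zeros);
  int kept = 0;
  long acc_hyper = 0, try_hyper = 0, acc_gamma = 0, try_gamma = 0;

  for (int it = 0; it < n_steps; ++it) {
    // --- hyperparameter move -------------------------------------------
    {
      ++try_hyper;
      double h2 = reflect(h + step_h * (2.0 * rng.unif() - 1.0), h_lo, h_hi);
      double rho2 = rho_fixed
        ? rho
        : reflect(rho + step_rho * (2.0 * rng.unif() - 1.0), 0.0, 1.0);
      double l10pi2 = sparse_on
        ? reflect(l10pi + step_pi * (2.0 * rng.unif() - 1.0),
                  log10pi_min, log10pi_max)
        : l10pi;
      double pi2 = std::pow(10.0, l10pi2);
      LikState prop = eval_lik(UtX, Uty, d, idx_vec(), h2, rho2, pi2);
      double prop_prior = log_gamma_prior(incl.size(), p, pi2);
      double lr = (prop.loglik + prop_prior) - (cur.loglik + cur_prior);
      if (prop.ok && std::log(rng.unif() + 1e-300) < lr) {
        h = h2; rho = rho2; l10pi = l10pi2;
        cur = prop; cur_prior = prop_prior;
        ++acc_hyper;
      }
    }
    // --- inclusion-set move --------------------------------------------
    if (sparse_on) {
      ++try_gamma;
      const uword m = incl.size();
      double pa, pr, ps;
      move_probs(m, p, s_max, pa, pr, ps);
      if (pa + pr + ps > 0.0) {
      double u = rng.unif();
      int move = (u < pa) ? 0 : (u < pa + pr ? 1 : 2); // add/remove/swap

      std::vector<uword> prop_incl = incl;
      double log_q = 0.0;          // log q(reverse)/q(forward)
      if (move == 0) {
        uword pick = rng.unif_int(p - m), seen = 0, snp = 0;
        for (uword j = 0; j < p; ++j)
          if (!in_set[j]) { if (seen == pick) { snp = j; break; } ++seen; }
        prop_incl.push_back(snp);
        double pa2, pr2, ps2;
        move_probs(m + 1, p, s_max, pa2, pr2, ps2);
        log_q = std::log(pr2 / double(m + 1)) -
                std::log(pa / double(p - m));
      } else if (move == 1) {
        uword pos = rng.unif_int(m);
        prop_incl.erase(prop_incl.begin() + pos);
        double pa2, pr2, ps2;
        move_probs(m - 1, p, s_max, pa2, pr2, ps2);
        log_q = std::log(pa2 / double(p - m + 1)) -
                std::log(pr / double(m));
      } else {
        uword pos = rng.unif_int(m);
        uword pick = rng.unif_int(p - m), seen = 0, snp = 0;
        for (uword j = 0; j < p; ++j)
          if (!in_set[j]) { if (seen == pick) { snp = j; break; } ++seen; }
        prop_incl[pos] = snp;
      }
      double pi_val = std::pow(10.0, l10pi);
      LikState prop = eval_lik(UtX, Uty, d, uvec(prop_incl), h, rho, pi_val);
      double prop_prior = log_gamma_prior(prop_incl.size(), p, pi_val);
      double lr = (prop.loglik + prop_prior) - (cur.loglik + cur_prior) + log_q;
      if (prop.ok && std::log(rng.unif() + 1e-300) < lr) {
        for (uword j : incl) in_set[j] = 0;
        incl = prop_incl;
        for (uword j : incl) in_set[j] = 1;
        cur = prop; cur_prior = prop_prior;
        ++acc_gamma;
      }
      }
    }
    // --- record ---------------------------------------------------------
    if (it >= n_burn && (it - n_burn) % thin == 0) {
      ch_h(kept) = h;
      ch_rho(kept) = rho;
      ch_pi(kept) = l10pi;
      ch_m(kept) = static_cast<int>(incl.size());
      // Rao-Blackwellized per-SNP accumulators
      vec resid = Uty;
      if (!incl.empty()) {
        uvec iv = idx_vec();
        for (uword k = 0; k < iv.n_elem; ++k) {
          pip(iv(k)) += 1.0;
          beta_acc(iv(k)) += cur.beta_hat(k);
        }
        resid -= UtX.cols(iv) * cur.beta_hat;
      }
      const double sb2 = h * (1.0 - rho) / (1.0 - h);
      vec hr = cur.hinv % resid;
      alpha_acc += (sb2 / double(p)) * (UtX.t() * hr);
      ++kept;
    }
  }

  double kd = std::max(kept, 1);
  return Rcpp::List::create(
    Rcpp::Named("h") = ch_h.head(kept),
    Rcpp::Named("rho") = ch_rho.head(kept),
    Rcpp::Named("log10_pi") = ch_pi.head(kept),
    Rcpp::Named("n_gamma") = ch_m.head(kept),
    Rcpp::Named("pip") = pip / kd,
    Rcpp::Named("beta") = beta_acc / kd,
    Rcpp::Named("alpha") = alpha_acc / kd,
    Rcpp::Named("accept_hyper") = double(acc_hyper) / std::max(try_hyper, 1L),
    Rcpp::Named("accept_gamma") = double(acc_gamma) / std::max(try_gamma, 1L),
    Rcpp::Named("n_kept") = kept);
}
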