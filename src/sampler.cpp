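#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the Poisson random-effects model
//   C_i ~ Poisson(exp(mu + nu_i) * E_i),  nu_i ~ N(0, sigma^2)
// with one of three priors on sigma:
//   prior_type 0: sigma ~ Uniform(lb, ub)
//   prior_type 1: LB ~ U(0, lb_hyper_max), UB ~ U(LB, ub_hyper_max),
//                 sigma | LB,UB ~ Uniform(LB, UB)
//   prior_type 2: tau = sigma^-2 ~ Gamma(gamma_shape, gamma_rate),
//                 updated by its conjugate Gibbs draw.
// mu and each nu_i move by random-walk Metropolis; proposal scales adapt
// during burn-in only (log-scale Robbins-Monro toward 35% acceptance), so
// the kept chain is Markovian.  Uses R's RNG: set.seed() on the R side
// makes runs reproducible.

static inline double runif1() { return unif_rand(); }

// [[Rcpp::export(name = ".sampler_cpp")]]
List sampler_cpp(IntegerVector C, NumericVector E,
                 int prior_type, double lb, double ub,
                 double lb_hyper_max, double ub_hyper_max,
                 double gamma_shape, double gamma_rate,
                 int n_iter, int n_burnin, int thin,
                 double init_mu, double init_sigma,
                 double scale_mu, double scale_nu, double scale_sigma,
                 bool adapt) {
  const int I = C.size();
  const int n_keep = n_iter / thin;

  std::vector<double> nu(I, 0.0), expnu(I, 1.0);
  double mu = init_mu, sigma = init_sigma;
  double cur_lb = lb, cur_ub = ub;
  if (prior_type == 1) {           // hierarchical: start bounds wide open
    cur_lb = 0.0;
    cur_ub = ub_hyper_max;
    if (sigma <= cur_lb || sigma >= cur_ub)
      sigma = 0.5 * (cur_lb + cur_ub);
  }

  double sumC = 0.0;
  for (int i = 0; i < I; ++i) sumC += C[i];

  NumericVector draws_mu(n_keep), draws_sigma(n_keep);
  NumericMatrix draws_nu(n_keep, I);
  NumericVector draws_lb(prior_type == 1 ? n_keep : 0),
                draws_ub(prior_type == 1 ? n_keep : 0);

  double s_mu = scale_mu, s_nu = scale_nu, s_sigma = scale_sigma;
  int acc_mu = 0, acc_nu = 0, acc_sigma = 0, try_sigma = 0;
  int bat_mu = 0, bat_nu = 0, bat_try_nu = 0, bat_sigma = 0, bat_try_sigma = 0;
  const int batch = 50;

  const int total = n_burnin + n_iter;
  for (int it = 0; it < total; ++it) {
    // --- mu: random-walk Metropolis -----------------------------------
    {
      double prop = mu + s_mu * norm_rand();
      // |mu| > 50 is far outside any identifiable posterior; rejecting
      // there guards exp() overflow on degenerate inputs
      if (std::abs(prop) <= 50.0) {
        // delta log-lik = sumC*(prop-mu) - sum_i E_i e^{nu_i}(e^prop - e^mu)
        double see = 0.0;
        for (int i = 0; i < I; ++i) see += E[i] * expnu[i];
        double dl = sumC * (prop - mu) - see * (std::exp(prop) - std::exp(mu));
        if (dl >= 0.0 || runif1() < std::exp(dl)) {
          mu = prop; ++acc_mu; ++bat_mu;
        }
      }
    }
    const double emu = std::exp(mu);

    // --- nu_i: single-site random-walk Metropolis ---------------------
    // Mixture proposal (symmetric, hence valid): half the moves use the
    // adapted global scale, half a scale proportional to the current
    // sigma, so the random effects keep moving when sigma is near zero
    // (the "funnel" regime of vague precision priors).
    {
      const double inv2s2 = 0.5 / (sigma * sigma);
      for (int i = 0; i < I; ++i) {
        bool global = runif1() < 0.5;
        double sd = global ? s_nu : std::max(0.5 * sigma, 1e-3);
        if (global) ++bat_try_nu;
        double prop = nu[i] + sd * norm_rand();
        if (std::abs(prop) > 50.0) continue;
        double eprop = std::exp(prop);
        double dl = C[i] * (prop - nu[i]) - E[i] * emu * (eprop - expnu[i])
                    - (prop * prop - nu[i] * nu[i]) * inv2s2;
        if (dl >= 0.0 || runif1() < std::exp(dl)) {
          nu[i] = prop; expnu[i] = eprop; ++acc_nu;
          if (global) ++bat_nu;
        }
      }
    }

    // --- recentering Gibbs step on mu ---------------------------------
    // The likelihood depends on (mu, nu) only through theta_i = mu+nu_i,
    // so with a flat prior on mu its conditional given theta and sigma is
    // N(mean(theta), sigma^2/I).  Drawing mu there and resetting
    // nu_i = theta_i - mu decorrelates mu from the random effects.
    {
      double nbar = 0.0;
      for (int i = 0; i < I; ++i) nbar += nu[i];
      nbar /= I;
      const double tbar = mu + nbar;
      const double csd = sigma / std::sqrt((double)I);   // exact conditional
      const double psd = std::min(csd, 2.0);             // clamped proposal
      double mu_new = tbar + psd * norm_rand();
      bool accept = true;
      if (psd < csd) {
        // independence-MH correction: target N(tbar, csd^2), proposal
        // N(tbar, psd^2); exact Gibbs (always accept) when psd == csd
        double zt = (mu_new - tbar) / csd, zc = (mu - tbar) / csd;
        double zpt = (mu_new - tbar) / psd, zpc = (mu - tbar) / psd;
        double la = -0.5 * (zt * zt - zc * zc) + 0.5 * (zpt * zpt - zpc * zpc);
        accept = (la >= 0.0) || (runif1() < std::exp(la));
      }
      if (accept && std::abs(mu_new) <= 50.0) {
        double shift = mu_new - mu;
        for (int i = 0; i < I; ++i) {
          nu[i] -= shift;
          expnu[i] = std::exp(nu[i]);
        }
        mu = mu_new;
      }
    }
    const double emu2 = std::exp(mu);   // mu changed above

    // --- funnel scaling move: (sigma, nu) -> (c sigma, c nu) ----------
    // Group move along the funnel axis; the Gaussian prior terms cancel,
    // leaving  dlog = dloglik + log c + dlog p(sigma)  (p flat for the
    // uniform families, gamma-on-precision density otherwise).
    {
      double c = std::exp(0.4 * norm_rand());
      double sig_prop = c * sigma;
      bool ok = true;
      if (prior_type == 2) {
        if (sig_prop < 1e-8 || sig_prop > 1e8) ok = false;
      } else {
        if (sig_prop <= cur_lb || sig_prop >= cur_ub) ok = false;
      }
      if (ok) {
        double dl = std::log(c);
        (void)emu;
        if (prior_type == 2) {
          // gamma density on tau = sigma^-2 mapped to the sigma scale
          double t_new = 1.0 / (sig_prop * sig_prop),
                 t_old = 1.0 / (sigma * sigma);
          dl += (gamma_shape - 1.0) * (std::log(t_new) - std::log(t_old))
                - gamma_rate * (t_new - t_old)
                - 3.0 * (std::log(sig_prop) - std::log(sigma));
        }
        bool overflow = false;
        for (int i = 0; i < I && !overflow; ++i) {
          double nprop = c * nu[i];
          if (std::abs(nprop) > 50.0) { overflow = true; break; }
          dl += C[i] * (nprop - nu[i])
                - E[i] * emu2 * (std::exp(nprop) - expnu[i]);
        }
        if (!overflow && (dl >= 0.0 || runif1() < std::exp(dl))) {
          sigma = sig_prop;
          for (int i = 0; i < I; ++i) {
            nu[i] *= c;
            expnu[i] = std::exp(nu[i]);
          }
        }
      }
    }

    double ss_nu = 0.0;
    for (int i = 0; i < I; ++i) ss_nu += nu[i] * nu[i];

    // --- sigma (and hierarchical bounds) ------------------------------
    if (prior_type == 2) {
      // conjugate Gibbs draw for tau given nu
      double tau = R::rgamma(gamma_shape + 0.5 * I,
                             1.0 / (gamma_rate + 0.5 * ss_nu));
      sigma = 1.0 / std::sqrt(tau);
    } else {
      ++try_sigma; ++bat_try_sigma;
      double prop = sigma + s_sigma * norm_rand();
      if (prop > cur_lb && prop < cur_ub && prop > 0.0) {
        // flat prior on sigma within bounds; N(0,sigma^2) likelihood of nu
        double dl = -I * (std::log(prop) - std::log(sigma))
                    - 0.5 * ss_nu * (1.0 / (prop * prop) -
                                     1.0 / (sigma * sigma));
        if (dl >= 0.0 || runif1() < std::exp(dl)) {
          sigma = prop; ++acc_sigma; ++bat_sigma;
        }
      }
      if (prior_type == 1) {
        // LB | rest ~ flat on (0, min(sigma, lb_hyper_max, UB)) times the
        // sigma-prior normalisation 1/(UB-LB) and UB-prior 1/(ub_max-LB)
        double lb_prop = cur_lb + 0.25 * lb_hyper_max * norm_rand();
        double lb_cap = std::min(std::min(sigma, lb_hyper_max), cur_ub);
        if (lb_prop >= 0.0 && lb_prop < lb_cap) {
          double dl = -std::log(cur_ub - lb_prop) + std::log(cur_ub - cur_lb)
                      - std::log(ub_hyper_max - lb_prop)
                      + std::log(ub_hyper_max - cur_lb);
          if (dl >= 0.0 || runif1() < std::exp(dl)) cur_lb = lb_prop;
        }
        double ub_prop = cur_ub + 0.25 * ub_hyper_max * norm_rand();
        double ub_floor = std::max(sigma, cur_lb);
        if (ub_prop > ub_floor && ub_prop <= ub_hyper_max) {
          double dl = -std::log(ub_prop - cur_lb) + std::log(cur_ub - cur_lb);
          if (dl >= 0.0 || runif1() < std::exp(dl)) cur_ub = ub_prop;
        }
      }
    }

    // --- adaptation (burn-in only) ------------------------------------
    if (adapt && it < n_burnin && ((it + 1) % batch == 0)) {
      double r_mu = bat_mu / (double)batch;
      s_mu *= std::exp((r_mu - 0.35));
      if (bat_try_nu > 0) {
        double r_nu = bat_nu / (double)bat_try_nu;
        s_nu *= std::exp((r_nu - 0.35));
      }
      if (prior_type != 2 && bat_try_sigma > 0) {
        double r_s = bat_sigma / (double)bat_try_sigma;
        s_sigma *= std::exp((r_s - 0.35));
        // keep sigma steps sane relative to the support width
        double w = cur_ub - cur_lb;
        if (s_sigma > w) s_sigma = w;
        if (s_sigma < 1e-4) s_sigma = 1e-4;
      }
      if (s_mu < 1e-5) s_mu = 1e-5;
      if (s_nu < 1e-5) s_nu = 1e-5;
      if (s_mu > 10.0) s_mu = 10.0;
      if (s_nu > 10.0) s_nu = 10.0;
      bat_mu = bat_nu = bat_try_nu = bat_sigma = bat_try_sigma = 0;
    }

    // --- record -------------------------------------------------------
    if (it >= n_burnin) {
      int k = it - n_burnin;
      if (k % thin == 0) {
        int row = k / thin;
        if (row < n_keep) {
          draws_mu[row] = mu;
          draws_sigma[row] = sigma;
          for (int i = 0; i < I; ++i) draws_nu(row, i) = nu[i];
          if (prior_type == 1) { draws_lb[row] = cur_lb; draws_ub[row] = cur_ub; }
        }
      }
    }
  }

  return List::create(
    _["mu"] = draws_mu, _["sigma"] = draws_sigma, _["nu"] = draws_nu,
    _["lb"] = draws_lb, _["ub"] = draws_ub,
    _["accept"] = NumericVector::create(
      _["mu"] = acc_mu / (double)total,
      _["nu"] = acc_nu / (double)(total * I),
      _["sigma"] = try_sigma > 0 ? acc_sigma / (double)try_sigma : NA_REAL),
    _["scales"] = NumericVector::create(
      _["mu"] = s_mu, _["nu"] = s_nu, _["sigma"] = s_sigma));
}
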