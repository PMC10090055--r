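#include <Rcpp.h>
using namespace Rcpp;

// Random-walk Metropolis sampler for the power-law attenuation model.
// Parameters: shared exponent b (normal prior) and one 100-m flux per
// deployment (uniform prior on (f_lo, f_hi)). Likelihood kernel is
// exp(-SSNM/2); all arithmetic is in log space. Draws go through R's RNG so
// set.seed() in the caller makes the chain reproducible.
//
// blockwise = true : all parameters proposed jointly, one accept/reject per
//                    iteration (the algorithm as described).
// blockwise = false: componentwise sweeps (b, then each flux) using cached
//                    per-deployment misfit contributions.
// adapt = true     : during the first 3/4 of burn-in a global proposal scale
//                    is retuned every 250 iterations toward 10-40%
//                    acceptance, then frozen before any retained sample.

// [[Rcpp::export]]
List metropolis_chain_cpp(NumericVector flux, NumericVector sdv,
                          NumericVector depth, IntegerVector dep, int n_dep,
                          double b_init, NumericVector f_init,
                          double b_prior_mean, double b_prior_sd,
                          double f_lo, double f_hi,
                          double prop_b, double prop_f,
                          double n_iter, double n_burn, int thin,
                          bool blockwise, bool adapt) {
  const int m = flux.size();
  std::vector<double> lz(m), w(m);
  for (int j = 0; j < m; ++j) {
    lz[j] = std::log(depth[j] / 100.0);
    w[j] = 1.0 / (sdv[j] * sdv[j]);
  }

  double b = b_init;
  std::vector<double> f(f_init.begin(), f_init.end());

  // measurement index ranges per deployment (caller sorts by deployment)
  std::vector<int> start(n_dep + 1, 0);
  for (int j = 0; j < m; ++j) start[dep[j] + 1]++;
  for (int d = 0; d < n_dep; ++d) start[d + 1] += start[d];

  // per-deployment SSNM contributions at current state
  std::vector<double> part(n_dep);
  auto dep_part = [&](int d, double bb, double fd) {
    double s = 0.0;
    for (int j = start[d]; j < start[d + 1]; ++j) {
      double r = flux[j] - fd * std::exp(-bb * lz[j]);
      s += r * r * w[j];
    }
    return s;
  };
  auto full_ssnm = [&](double bb, const std::vector<double>& ff) {
    double s = 0.0;
    for (int j = 0; j < m; ++j) {
      double r = flux[j] - ff[dep[j]] * std::exp(-bb * lz[j]);
      s += r * r * w[j];
    }
    return s;
  };
  for (int d = 0; d < n_dep; ++d) part[d] = dep_part(d, b, f[d]);
  double cur = full_ssnm(b, f);
  double lp_b = R::dnorm(b, b_prior_mean, b_prior_sd, 1);

  const long N = (long)n_iter, B = (long)n_burn;
  const long n_keep = (N - B + thin - 1) / thin;
  NumericVector b_out(n_keep);
  NumericMatrix f_out(n_keep, n_dep);

  double scale = 1.0;
  const long adapt_until = adapt ? (3 * B) / 4 : 0;
  long win_acc = 0, win_n = 0;
  double post_acc = 0.0, post_n = 0.0;
  long k = 0;
  std::vector<double> fprop(n_dep);

  for (long it = 0; it < N; ++it) {
    if (blockwise) {
      double bprop = b + R::rnorm(0.0, prop_b * scale);
      bool in_support = true;
      for (int d = 0; d < n_dep; ++d) {
        fprop[d] = f[d] + R::rnorm(0.0, prop_f * scale);
        if (fprop[d] < f_lo || fprop[d] > f_hi) in_support = false;
      }
      bool accepted = false;
      if (in_support) {
        double newss = full_ssnm(bprop, fprop);
        double lp_new = R::dnorm(bprop, b_prior_mean, b_prior_sd, 1);
        double la = -0.5 * (newss - cur) + (lp_new - lp_b);
        if (std::log(R::runif(0.0, 1.0)) < la) {
          b = bprop; f = fprop; cur = newss; lp_b = lp_new;
          accepted = true;
        }
      } else {
        (void)R::runif(0.0, 1.0);  // keep the draw count state-independent
      }
      if (it < adapt_until) { win_acc += accepted; ++win_n; }
      if (it >= B) { post_acc += accepted; post_n += 1.0; }
    } else {
      // exponent update (touches every deployment's contribution)
      double bprop = b + R::rnorm(0.0, prop_b * scale);
      double newss = full_ssnm(bprop, f);
      double lp_new = R::dnorm(bprop, b_prior_mean, b_prior_sd, 1);
      bool acc_b = std::log(R::runif(0.0, 1.0)) < -0.5 * (newss - cur) + (lp_new - lp_b);
      if (acc_b) {
        b = bprop; cur = newss; lp_b = lp_new;
        for (int d = 0; d < n_dep; ++d) part[d] = dep_part(d, b, f[d]);
      }
      double acc_cnt = acc_b ? 1.0 : 0.0;
      for (int d = 0; d < n_dep; ++d) {
        double fp = f[d] + R::rnorm(0.0, prop_f * scale);
        double u = R::runif(0.0, 1.0);
        if (fp < f_lo || fp > f_hi) continue;
        double newpart = dep_part(d, b, fp);
        if (std::log(u) < -0.5 * (newpart - part[d])) {
          cur += newpart - part[d];
          part[d] = newpart;
          f[d] = fp;
          acc_cnt += 1.0;
        }
      }
      double frac = acc_cnt / (n_dep + 1.0);
      if (it < adapt_until) { win_acc += (frac >= 0.5); ++win_n; }
      if (it >= B) { post_acc += frac; post_n += 1.0; }
    }

    if (adapt && it < adapt_until && win_n >= 250) {
      double rate = (double)win_acc / (double)win_n;
      if (rate < 0.10) scale *= 0.5;
      else if (rate > 0.40) scale *= 1.5;
      win_acc = 0; win_n = 0;
    }

    if (it >= B && ((it - B) % thin == 0)) {
      b_out[k] = b;
      for (int d = 0; d < n_dep; ++d) f_out(k, d) = f[d];
      ++k;
    }
    if ((it & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["b_samples"] = b_out, _["f_samples"] = f_out,
                      _["acceptance_rate"] = post_n > 0 ? post_acc / post_n : 0.0,
                      _["scale"] = scale);
}
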