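// Gibbs sampler for the multinomial-logit structured additive model.
//
// Each non-reference category k in {1,2} is updated through the standard
// partial-logit reduction: conditional on the other category's predictor,
// membership in category k is Bernoulli with logit eta_k - C, where
// C = log(1 + exp(eta_other)).  Polya-Gamma augmentation then gives
// closed-form Gaussian updates for the fixed effects, the P-spline
// coefficients (RW2 prior), the iid PSU effects and the intrinsic-MRF
// region effects, and conjugate inverse-gamma updates for the variances.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ----------------------- PG(1, z) sampler ------------------------------
// Devroye-style alternating-series rejection sampler for the Jacobi J*(1,z)
// distribution; PG(1, z) = J*(1, z/2) / 4.

static const double PG_TRUNC = 0.64;

static double pg_a_coef(int n, double x) {
  double k = n + 0.5;
  if (x > PG_TRUNC)
    return M_PI * k * std::exp(-0.5 * k * k * M_PI * M_PI * x);
  return M_PI * k * std::pow(2.0 / (M_PI * x), 1.5) * std::exp(-2.0 * k * k / x);
}

// CDF at x of inverse-Gaussian with mean 1/z, shape 1 (z >= 0, z = 0 ok)
static double pg_pigauss(double x, double z) {
  double rx = 1.0 / std::sqrt(x);
  double head = R::pnorm(rx * (x * z - 1.0), 0.0, 1.0, 1, 0);
  double ltail = 2.0 * z + R::pnorm(-rx * (x * z + 1.0), 0.0, 1.0, 1, 1);
  return head + std::exp(ltail);
}

// inverse-Gaussian(1/z, 1) truncated to (0, t]
static double pg_rtigauss(double z, double t) {
  z = std::fabs(z);
  double x = t + 1.0;
  if (z < 1.0 / t) {  // mu = 1/z > t: rejection from truncated inverse chi^2
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

static double pg_draw1(double zin) {
  double z = 0.5 * std::fabs(zin);
  double t = PG_TRUNC;
  double K = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double p = (0.5 * M_PI / K) * std::exp(-K * t);
  double q = 2.0 * std::exp(-z) * pg_pigauss(t, z);
  double x;
  for (;;) {
    double u = unif_rand();
    if (u < p / (p + q)) {
      x = t + exp_rand() / K;           // truncated exponential tail
    } else {
      x = pg_rtigauss(z, t);            // truncated inverse-Gaussian head
    }
    double s = pg_a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    bool accept = false, reject = false;
    while (!accept && !reject) {
      ++n;
      if (n % 2 == 1) {
        s -= pg_a_coef(n, x);
        if (y <= s) accept = true;
      } else {
        s += pg_a_coef(n, x);
        if (y > s) reject = true;
      }
    }
    if (accept) break;
  }
  return 0.25 * x;
}

// [[Rcpp::export(name = ".rpg_vec")]]
NumericVector rpg_vec(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pg_draw1(z[i]);
  return out;
}

// ------------------------- small helpers -------------------------------

static inline double log1p_exp(double x) {
  if (x > 0) return x + std::log1p(std::exp(-x));
  return std::log1p(std::exp(x));
}

static double rinvgamma(double shape, double rate) {
  return rate / R::rgamma(shape, 1.0);
}

// sample from N(A^{-1} v, A^{-1}) given precision A and linear term v
static arma::vec mvn_precision(const arma::mat &A, const arma::vec &v) {
  arma::mat U;
  if (!arma::chol(U, A))
    stop("non-positive-definite conditional precision in Gaussian update");
  arma::vec mean = arma::solve(arma::trimatu(U),
                               arma::solve(arma::trimatl(U.t()), v));
  arma::vec zdraw(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) zdraw[i] = norm_rand();
  return mean + arma::solve(arma::trimatu(U), zdraw);
}

// ------------------------------ sampler --------------------------------

// [[Rcpp::export(name = ".star_mcmc_cpp")]]
List star_mcmc_cpp(const arma::mat &X,
                   const arma::mat &Bw,        // n x (degree+1) spline weights
                   const arma::ivec &Bs,       // 0-based first column per row
                   int M,
                   const arma::mat &K,         // RW2 penalty (M x M)
                   const arma::ivec &psu,      // 0-based, length n
                   int n_psu,
                   const arma::ivec &region,   // 0-based, length n
                   int n_region,
                   const List &neighbors,      // per region, 0-based indices
                   const arma::ivec &y,        // labels 1..3
                   bool use_spline, bool use_psu, bool use_spatial,
                   int iters, int burnin, int thin,
                   double ig_a, double ig_b) {
  const int n = X.n_rows, p = X.n_cols;
  const int nb_cols = Bw.n_cols;
  if (iters <= burnin) stop("iterations must exceed burn-in");
  const int n_keep = (iters - burnin) / thin;
  if (n_keep < 1) stop("no retained draws under these settings");

  // neighbour structure
  std::vector<std::vector<int>> nb(n_region);
  arma::vec nnb(n_region, arma::fill::zeros);
  if (use_spatial) {
    for (int j = 0; j < n_region; ++j) {
      IntegerVector v = neighbors[j];
      nb[j] = std::vector<int>(v.begin(), v.end());
      nnb[j] = nb[j].size();
    }
  }

  // state
  arma::mat beta(p, 2, arma::fill::zeros);
  arma::mat gam(std::max(M, 1), 2, arma::fill::zeros);
  arma::mat bpsu(std::max(n_psu, 1), 2, arma::fill::zeros);
  arma::mat sreg(std::max(n_region, 1), 2, arma::fill::zeros);
  arma::vec tau2_a(2, arma::fill::ones), tau2_u(2, arma::fill::ones),
      tau2_s(2, arma::fill::ones);

  // predictor components per category
  arma::mat CX(n, 2, arma::fill::zeros), CF(n, 2, arma::fill::zeros),
      CB(n, 2, arma::fill::zeros), CS(n, 2, arma::fill::zeros);

  // storage
  arma::cube beta_out(p, 2, n_keep);
  arma::cube gam_out(use_spline ? M : 0, 2, use_spline ? n_keep : 0);
  arma::cube b_out(use_psu ? n_psu : 0, 2, use_psu ? n_keep : 0);
  arma::cube s_out(use_spatial ? n_region : 0, 2, use_spatial ? n_keep : 0);
  arma::mat tau2_out(6, n_keep, arma::fill::zeros);
  arma::vec dev_out(n_keep);

  arma::vec w(n), zvec(n), r(n), Coff(n);

  int keep = 0;
  for (int it = 1; it <= iters; ++it) {
    for (int k = 0; k < 2; ++k) {
      const int o = 1 - k;
      // offsets from the competing category
      for (int i = 0; i < n; ++i)
        Coff[i] = log1p_exp(CX(i, o) + CF(i, o) + CB(i, o) + CS(i, o));
      // Polya-Gamma draws and pseudo-observations
      for (int i = 0; i < n; ++i) {
        double lam = CX(i, k) + CF(i, k) + CB(i, k) + CS(i, k) - Coff[i];
        double wi = pg_draw1(lam);
        w[i] = wi;
        double kap = (y[i] == k + 1 ? 0.5 : -0.5);
        zvec[i] = kap / wi + Coff[i];
      }

      // ---- fixed effects (flat prior) ----
      r = zvec - CF.col(k) - CB.col(k) - CS.col(k);
      {
        arma::mat Xw = X.each_col() % w;
        arma::mat A = X.t() * Xw;
        arma::vec v = X.t() * (w % r);
        beta.col(k) = mvn_precision(A, v);
        CX.col(k) = X * beta.col(k);
      }

      // ---- P-spline coefficients ----
      if (use_spline) {
        r = zvec - CX.col(k) - CB.col(k) - CS.col(k);
        arma::mat A = K / tau2_a[k];
        arma::vec v(M, arma::fill::zeros);
        for (int i = 0; i < n; ++i) {
          const int c0 = Bs[i];
          const double wi = w[i], wri = wi * r[i];
          for (int a = 0; a < nb_cols; ++a) {
            const double ba = Bw(i, a);
            if (ba == 0.0) continue;
            v[c0 + a] += ba * wri;
            for (int b2 = 0; b2 < nb_cols; ++b2)
              A(c0 + a, c0 + b2) += ba * Bw(i, b2) * wi;
          }
        }
        gam.col(k) = mvn_precision(A, v);
        // centre the fitted smooth; constant shifts live in the RW2 null space
        arma::vec f(n);
        for (int i = 0; i < n; ++i) {
          double fi = 0.0;
          for (int a = 0; a < nb_cols; ++a) fi += Bw(i, a) * gam(Bs[i] + a, k);
          f[i] = fi;
        }
        double c = arma::mean(f);
        gam.col(k) -= c;
        beta(0, k) += c;
        CX.col(k) += c;
        CF.col(k) = f - c;
        double quad = arma::as_scalar(gam.col(k).t() * K * gam.col(k));
        tau2_a[k] = rinvgamma(ig_a + 0.5 * (M - 2), ig_b + 0.5 * quad);
      }

      // ---- iid PSU effects ----
      if (use_psu) {
        r = zvec - CX.col(k) - CF.col(k) - CS.col(k);
        arma::vec sw(n_psu, arma::fill::zeros), swr(n_psu, arma::fill::zeros);
        for (int i = 0; i < n; ++i) {
          sw[psu[i]] += w[i];
          swr[psu[i]] += w[i] * r[i];
        }
        for (int u = 0; u < n_psu; ++u) {
          double prec = sw[u] + 1.0 / tau2_u[k];
          bpsu(u, k) = swr[u] / prec + norm_rand() / std::sqrt(prec);
        }
        for (int i = 0; i < n; ++i) CB(i, k) = bpsu(psu[i], k);
        tau2_u[k] = rinvgamma(ig_a + 0.5 * n_psu,
                              ig_b + 0.5 * arma::dot(bpsu.col(k), bpsu.col(k)));
      }

      // ---- intrinsic-MRF region effects ----
      if (use_spatial) {
        r = zvec - CX.col(k) - CF.col(k) - CB.col(k);
        arma::vec sw(n_region, arma::fill::zeros), swr(n_region, arma::fill::zeros);
        for (int i = 0; i < n; ++i) {
          sw[region[i]] += w[i];
          swr[region[i]] += w[i] * r[i];
        }
        for (int j = 0; j < n_region; ++j) {
          double nbsum = 0.0;
          for (int j2 : nb[j]) nbsum += sreg(j2, k);
          double pr_prec = nnb[j] / tau2_s[k];
          double prec = sw[j] + pr_prec;
          double mean = (swr[j] + (pr_prec > 0 ? pr_prec * nbsum / nnb[j] : 0.0)) / prec;
          sreg(j, k) = mean + norm_rand() / std::sqrt(prec);
        }
        // identifiability: sum-to-zero, level absorbed by the intercept
        double ms = arma::mean(sreg.col(k));
        sreg.col(k) -= ms;
        beta(0, k) += ms;
        CX.col(k) += ms;
        for (int i = 0; i < n; ++i) CS(i, k) = sreg(region[i], k);
        double quad = 0.0;
        for (int j = 0; j < n_region; ++j)
          for (int j2 : nb[j])
            quad += sreg(j, k) * (sreg(j, k) - sreg(j2, k));
        // quad = s' (D - A) s with D = diag(N_j), A the adjacency matrix
        tau2_s[k] = rinvgamma(ig_a + 0.5 * (n_region - 1), ig_b + 0.5 * quad);
      }
    }

    if (it > burnin && (it - burnin) % thin == 0) {
      beta_out.slice(keep) = beta;
      if (use_spline) gam_out.slice(keep) = gam;
      if (use_psu) b_out.slice(keep) = bpsu;
      if (use_spatial) s_out.slice(keep) = sreg;
      tau2_out(0, keep) = tau2_a[0]; tau2_out(1, keep) = tau2_a[1];
      tau2_out(2, keep) = tau2_u[0]; tau2_out(3, keep) = tau2_u[1];
      tau2_out(4, keep) = tau2_s[0]; tau2_out(5, keep) = tau2_s[1];
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        double e1 = CX(i, 0) + CF(i, 0) + CB(i, 0) + CS(i, 0);
        double e2 = CX(i, 1) + CF(i, 1) + CB(i, 1) + CS(i, 1);
        double m = std::max(0.0, std::max(e1, e2));
        double lse = m + std::log(std::exp(-m) + std::exp(e1 - m) + std::exp(e2 - m));
        double ey = (y[i] == 1 ? e1 : (y[i] == 2 ? e2 : 0.0));
        ll += ey - lse;
      }
      dev_out[keep] = -2.0 * ll;
      if (!std::isfinite(dev_out[keep])) stop("divergent deviance at retained draw");
      ++keep;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["beta"] = beta_out, _["gamma"] = gam_out, _["b"] = b_out,
      _["s"] = s_out, _["tau2"] = tau2_out, _["deviance"] = dev_out);
}
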