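// Blocked Gibbs sampler for the phylogenetic varying-effects regression.
//
// Model (non-centered parameterization):
//   y_i = alpha_bar + s1*(L u1)[s] + s2*u2[s]
//         + (beta_bar + s3*(L u3)[s] + s4*u4[s]) * x_i + eps_i,
//   eps ~ N(0, sigma^2), u* ~ N(0, I), alpha_bar ~ N(m_a, 1),
//   beta_bar ~ N(0, 1), sigma and all four scales s* ~ Exp(1).
//
// Location block theta = (alpha_bar, beta_bar, u1..u4) is jointly Gaussian
// given the scales and is sampled by a Cholesky solve of its conditional
// precision. Each scale enters the mean linearly under non-centering, so its
// full conditional is a zero-truncated normal. The residual sd is updated by
// slice sampling on the log scale. Uses R's RNG throughout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double rtnorm_pos(double m, double s) {
  // N(m, s^2) truncated to (0, Inf)
  double alpha = -m / s;
  if (alpha < 0.45) {
    for (int i = 0; i < 10000; ++i) {
      double x = m + s * norm_rand();
      if (x > 0.0) return x;
    }
    return 1e-12;
  }
  // Robert (1995) exponential rejection on the standardized scale
  double lambda = 0.5 * (alpha + std::sqrt(alpha * alpha + 4.0));
  for (int i = 0; i < 100000; ++i) {
    double z = alpha + exp_rand() / lambda;
    double rho = std::exp(-0.5 * (z - lambda) * (z - lambda));
    if (unif_rand() < rho) return m + s * z;
  }
  return std::max(1e-12, m);
}

static double logpost_logscale_centered(double phi, double q, int S) {
  // p(sigma | centered effects a): sigma^-S exp(-q / (2 sigma^2)) * Exp(1)
  // prior * Jacobian of the log transform, with q = a' R^{-1} a
  double sig = std::exp(phi);
  return -S * phi - 0.5 * q / (sig * sig) - sig + phi;
}

static double slice_logscale_centered(double phi0, double q, int S) {
  double w = 1.0;
  double logy = logpost_logscale_centered(phi0, q, S) + std::log(unif_rand());
  double lo = phi0 - w * unif_rand();
  double hi = lo + w;
  for (int i = 0; i < 50 && logpost_logscale_centered(lo, q, S) > logy; ++i) lo -= w;
  for (int i = 0; i < 50 && logpost_logscale_centered(hi, q, S) > logy; ++i) hi += w;
  for (int i = 0; i < 200; ++i) {
    double phi = lo + unif_rand() * (hi - lo);
    if (logpost_logscale_centered(phi, q, S) >= logy) return phi;
    if (phi < phi0) lo = phi; else hi = phi;
  }
  return phi0;
}

static double logpost_logsigma(double phi, double ssr, int n) {
  double sig = std::exp(phi);
  // likelihood * Exp(1) prior * Jacobian
  return -n * phi - 0.5 * ssr / (sig * sig) - sig + phi;
}

static double slice_logsigma(double phi0, double ssr, int n) {
  double w = 1.0;
  double logy = logpost_logsigma(phi0, ssr, n) + std::log(unif_rand());
  double lo = phi0 - w * unif_rand();
  double hi = lo + w;
  for (int i = 0; i < 50 && logpost_logsigma(lo, ssr, n) > logy; ++i) lo -= w;
  for (int i = 0; i < 50 && logpost_logsigma(hi, ssr, n) > logy; ++i) hi += w;
  for (int i = 0; i < 200; ++i) {
    double phi = lo + unif_rand() * (hi - lo);
    if (logpost_logsigma(phi, ssr, n) >= logy) return phi;
    if (phi < phi0) lo = phi; else hi = phi;
  }
  return phi0;
}

// [[Rcpp::export(name = ".gibbs_chain")]]
List gibbs_chain(const arma::vec& y, const arma::vec& x,
                 const arma::uvec& species, const arma::mat& L,
                 bool include_bm, double prior_mean_alpha,
                 int n_iter, int n_warmup, int thin,
                 List init) {
  const int n = y.n_elem;
  const int S = L.n_rows;
  const int n_scales = include_bm ? 4 : 2;
  const int p = include_bm ? (2 + 4 * S) : (1 + 2 * S);

  // base design: columns [1 | (x) | Z1 | Z2 | (Z3 | Z4)]
  arma::mat W0(n, p, arma::fill::zeros);
  W0.col(0).ones();
  int off = 1;
  int col_beta = -1;
  if (include_bm) { col_beta = 1; W0.col(1) = x; off = 2; }
  arma::uvec block_start(n_scales), block_len(n_scales);
  for (int i = 0; i < n; ++i) {
    const int s = species(i) - 1;
    for (int j = 0; j < S; ++j) {
      W0(i, off + j) = L(s, j);            // Z1: phylogenetic intercept
    }
    W0(i, off + S + s) = 1.0;              // Z2: independent intercept
    if (include_bm) {
      for (int j = 0; j < S; ++j) {
        W0(i, off + 2 * S + j) = x(i) * L(s, j);  // Z3: phylogenetic slope
      }
      W0(i, off + 3 * S + s) = x(i);       // Z4: independent slope
    }
  }
  for (int c = 0; c < n_scales; ++c) {
    block_start(c) = off + c * S;
    block_len(c) = S;
  }

  const arma::mat G0 = W0.t() * W0;
  const arma::vec g0y = W0.t() * y;
  arma::vec m0(p, arma::fill::zeros);
  m0(0) = prior_mean_alpha;

  // state
  arma::vec theta = as<arma::vec>(init["theta"]);
  arma::vec scales = as<arma::vec>(init["scales"]);   // length n_scales
  double sigma = as<double>(init["sigma"]);

  const int n_keep = (n_iter - n_warmup) / thin;
  arma::mat draws(n_keep, p + n_scales + 1);
  arma::mat loglik(n_keep, n);
  int keep = 0;

  arma::vec dscale(p, arma::fill::ones);

  for (int it = 0; it < n_iter; ++it) {
    // --- location block ---
    for (int c = 0; c < n_scales; ++c) {
      dscale.subvec(block_start(c), block_start(c) + S - 1).fill(scales(c));
    }
    const double inv_s2 = 1.0 / (sigma * sigma);
    arma::mat A = (dscale * dscale.t()) % G0 * inv_s2;
    A.diag() += 1.0;
    arma::vec rhs = (dscale % g0y) * inv_s2 + m0;
    arma::mat U = arma::chol(A);           // A = U' U
    arma::vec mu = arma::solve(arma::trimatu(U),
                     arma::solve(arma::trimatl(U.t()), rhs));
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z(j) = norm_rand();
    theta = mu + arma::solve(arma::trimatu(U), z);

    // fitted values under current scales
    arma::vec f = W0 * (dscale % theta);

    // --- scale parameters (zero-truncated normal conditionals) ---
    for (int c = 0; c < n_scales; ++c) {
      arma::vec cvec = W0.cols(block_start(c), block_start(c) + S - 1) *
                       theta.subvec(block_start(c), block_start(c) + S - 1);
      arma::vec base = f - scales(c) * cvec;
      double cc = arma::dot(cvec, cvec);
      double s_new;
      if (cc < 1e-300) {
        s_new = exp_rand();
      } else {
        double cr = arma::dot(cvec, y - base);
        double v = sigma * sigma / cc;
        double m = (cr - sigma * sigma) / cc;   // exponential prior shift
        s_new = rtnorm_pos(m, std::sqrt(v));
      }
      scales(c) = s_new;
      f = base + s_new * cvec;
    }

    // --- interweaving: re-sample each scale given the centered effects ---
    // Holding a_c = scale_c * (L) u_c fixed, the scale's conditional depends
    // only on q = a' R^{-1} a = scale^2 * u'u; u is rescaled to compensate.
    // Breaks the tight coupling between scales and latent effects that makes
    // the pure non-centered Gibbs step mix slowly.
    for (int c = 0; c < n_scales; ++c) {
      arma::vec u = theta.subvec(block_start(c), block_start(c) + S - 1);
      double uu = arma::dot(u, u);
      if (uu < 1e-300 || scales(c) < 1e-300) continue;
      double q = scales(c) * scales(c) * uu;
      double s_new = std::exp(
        slice_logscale_centered(std::log(scales(c)), q, S));
      theta.subvec(block_start(c), block_start(c) + S - 1) =
        u * (scales(c) / s_new);
      scales(c) = s_new;
    }

    // --- residual sd (slice on log scale) ---
    double ssr = arma::dot(y - f, y - f);
    sigma = std::exp(slice_logsigma(std::log(sigma), ssr, n));

    if (it >= n_warmup && ((it - n_warmup) % thin == 0) && keep < n_keep) {
      for (int j = 0; j < p; ++j) draws(keep, j) = theta(j);
      for (int c = 0; c < n_scales; ++c) draws(keep, p + c) = scales(c);
      draws(keep, p + n_scales) = sigma;
      const double lc = -0.5 * std::log(2.0 * M_PI) - std::log(sigma);
      const double inv2 = 0.5 / (sigma * sigma);
      for (int i = 0; i < n; ++i) {
        const double r = y(i) - f(i);
        loglik(keep, i) = lc - r * r * inv2;
      }
      ++keep;
    }
  }

  return List::create(_["draws"] = draws, _["loglik"] = loglik,
                      _["p_loc"] = p, _["col_beta"] = col_beta + 1);
}
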