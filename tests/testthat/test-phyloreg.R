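# small shared dataset for the fitting tests
make_test_dataset <- function(seed = 1, beta_bar = 0.3, sigma = 0.05,
                              sds = c(0.1, 0.1, 0.1, 0.1), n_per = 30,
                              n_taxa = 8) {
  tr <- simulate_yule_tree(n_taxa, seed = seed)
  eff <- simulate_varying_effects(tr, 3, beta_bar, sds[1], sds[2], sds[3],
                                  sds[4], seed = seed + 1)
  rec <- simulate_measurements(eff, n_per,
                               bm_log_mean = seq(log(30), log(900),
                                                 length.out = n_taxa),
                               bm_log_sd = 0.2, sigma = sigma, seed = seed + 2)
  build_dataset(rec, "IFA", tr)
}

test_that("WAIC of a degenerate posterior equals the closed-form normal value", {
  # one observation y = 0, posterior fixed at mu = 0, sigma = 1:
  # lppd = log N(0|0,1), p_waic = 0, WAIC = -2 lppd = 1.8378771
  ll <- matrix(dnorm(0, 0, 1, log = TRUE), nrow = 10, ncol = 1)
  w <- compute_waic(ll)
  expect_equal(w$lppd, -0.918938533204673, tolerance = 1e-12)
  expect_equal(w$p_waic, 0, tolerance = 1e-12)
  expect_equal(w$waic, 1.83787706640935, tolerance = 1e-12)
})

test_that("WAIC matches the direct-formula oracle on hand-written draws", {
  set.seed(5)
  ll <- matrix(rnorm(15, -1, 0.3), nrow = 3, ncol = 5)  # 3 draws, 5 obs
  w <- compute_waic(ll)
  oracle <- bruteforce_waic(ll)
  expect_equal(w$lppd, oracle$lppd, tolerance = 1e-12)
  expect_equal(w$p_waic, oracle$p_waic, tolerance = 1e-12)
  expect_equal(w$waic, oracle$waic, tolerance = 1e-12)
  expect_gte(w$p_waic, 0)
  expect_equal(w$waic, -2 * (w$lppd - w$p_waic), tolerance = 1e-12)
  expect_error(compute_waic(ll[1, , drop = FALSE]), "2 posterior draws")
})

test_that("model comparison: identical fits tie; constant pointwise shift has zero SE", {
  set.seed(6)
  ll <- matrix(rnorm(40, -1, 0.2), nrow = 4, ncol = 10)
  w <- compute_waic(ll)
  cmp0 <- compare_models(w, w)
  expect_equal(cmp0$delta_waic, 0)
  expect_equal(cmp0$delta_se, 0)

  w2 <- compute_waic(ll - 0.25)  # every pointwise loglik shifted by -0.25
  cmp <- compare_models(w2, w)
  expect_equal(cmp$delta_waic, 10 * 0.5, tolerance = 1e-9)
  expect_equal(cmp$delta_se, 0, tolerance = 1e-9)
  expect_equal(cmp$preferred, "reduced")
  expect_error(compare_models(w, compute_waic(ll[, 1:5])), "different numbers")
})

test_that("posterior_summary: exact constants, normal quantile oracle, divergent chains flagged", {
  d <- tibble::tibble(theta = rep(3, 400), .chain = rep(1:2, each = 200),
                      .iteration = rep(1:200, 2))
  s <- posterior_summary(d)
  expect_equal(s$estimate, 3)
  expect_equal(s$conf.low, 3)
  expect_equal(s$conf.high, 3)

  set.seed(7)
  dn <- tibble::tibble(z = rnorm(100000), .chain = rep(1:2, each = 50000),
                       .iteration = rep(1:50000, 2))
  sn <- posterior_summary(dn, prob = 0.89)
  expect_equal(sn$conf.low, qnorm(0.055), tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(sn$conf.high, qnorm(0.945), tolerance = 0.02, ignore_attr = TRUE)

  bad <- tibble::tibble(z = c(rnorm(500, 0), rnorm(500, 5)),
                        .chain = rep(1:2, each = 500),
                        .iteration = rep(1:500, 2))
  sb <- posterior_summary(bad)
  expect_gt(sb$rhat, 1.05)
  expect_false(sb$converged)
})

test_that("variance shares: boundary cases and interval contract", {
  fake <- structure(list(
    draws = tibble::tibble(
      sigma_a_phy = c(0.3, 0.4, 0.5), sigma_a_sp = c(0, 0, 0),
      sigma_b_phy = c(0.2, 0.2, 0.2), sigma_b_sp = c(0.2, 0.2, 0.2),
      .chain = 1L, .iteration = 1:3),
    include_bm = TRUE), class = "phylo_regression")
  vs <- variance_shares(fake)
  expect_equal(vs$phylo_share[vs$component == "intercept"], 1)
  expect_equal(vs$phylo_share[vs$component == "slope"], 0.5)
  expect_equal(vs$n_skipped, c(0, 0))

  fake0 <- fake
  fake0$draws$sigma_a_phy <- c(0, 0.3, 0.3)
  fake0$draws$sigma_a_sp <- c(0, 0.3, 0.3)
  vs0 <- variance_shares(fake0)
  expect_equal(vs0$n_skipped[vs0$component == "intercept"], 1)
  expect_equal(vs0$phylo_share[vs0$component == "intercept"], 0.5)
})

test_that("the sampler recovers generating parameters on a synthetic dataset", {
  ds <- make_test_dataset(seed = 101)
  fit <- fit_varying_effects(ds, include_bm = TRUE, chains = 4, iter = 2000,
                             seed = 11)
  s <- posterior_summary(fit, pars = c("alpha_bar", "beta_bar", "sigma"))
  expect_true(all(s$rhat < 1.05, na.rm = TRUE))
  expect_equal(s$estimate[s$term == "sigma"], 0.05, tolerance = 0.25)
  expect_equal(s$estimate[s$term == "alpha_bar"], 3, tolerance = 0.15)
  # slope posterior near the realized species-mean slope (8 species only)
  eff <- attr(attr(ds, "effects"), "truth")
  expect_lt(abs(s$estimate[s$term == "beta_bar"] - 0.3), 0.35)
  expect_error(fit_varying_effects(ds, chains = 1), "2 chains")
  expect_error(fit_varying_effects(ds, warmup = 1.2), "warmup")
})

test_that("with zero generating sds and large n the slope posterior concentrates at truth", {
  ds <- make_test_dataset(seed = 103, sds = c(0, 0, 0, 0), sigma = 0.05,
                          n_per = 120)
  fit <- fit_varying_effects(ds, include_bm = TRUE, chains = 4, iter = 2000,
                             seed = 13)
  s <- posterior_summary(fit, pars = c("alpha_bar", "beta_bar"))
  expect_lt(abs(s$estimate[s$term == "beta_bar"] - 0.3), 0.03)
  expect_lt(abs(s$estimate[s$term == "alpha_bar"] - 3), 0.03)
  expect_true(all(s$rhat < 1.02))
})

test_that("with an identity correlation the fit matches the non-phylogenetic reduction", {
  ds <- make_test_dataset(seed = 107)
  S <- length(ds$species)
  I <- diag(S); dimnames(I) <- list(ds$species, ds$species)
  fit_tree <- fit_varying_effects(ds, chains = 2, iter = 2000, seed = 15, R = I)
  # star phylogeny = same identity correlation through the tree route
  star <- ape::read.tree(text = paste0("(", paste0(ds$species, ":1",
                                                   collapse = ","), ");"))
  ds2 <- ds
  ds2$tree <- star
  fit_star <- fit_varying_effects(ds2, chains = 2, iter = 2000, seed = 15)
  s1 <- posterior_summary(fit_tree, pars = c("alpha_bar", "beta_bar", "sigma"))
  s2 <- posterior_summary(fit_star, pars = c("alpha_bar", "beta_bar", "sigma"))
  mcse <- s1$std.error / sqrt(pmax(s1$ess, 1))
  expect_true(all(abs(s1$estimate - s2$estimate) <
                    3 * pmax(mcse, s1$std.error / 20) + 0.02))
})

test_that("pointwise lppd never improves when sigma is inflated on fixed draws", {
  ds <- make_test_dataset(seed = 109, n_per = 10)
  fit <- fit_varying_effects(ds, chains = 2, iter = 500, seed = 17)
  ll <- fit$loglik
  sig <- fit$draws$sigma
  lc <- -0.5 * log(2 * pi) - log(sig)
  # recover per-draw squared residuals from the stored normal log-density
  resid2 <- (matrix(lc, nrow(ll), ncol(ll)) - ll) * (2 * sig^2)
  for (c_ in c(1.5, 3)) {
    ll_inflated <- matrix(-0.5 * log(2 * pi) - log(sig * c_),
                          nrow(ll), ncol(ll)) - resid2 / (2 * (sig * c_)^2)
    lppd0 <- sum(log(colMeans(exp(ll))))
    lppd1 <- sum(log(colMeans(exp(ll_inflated))))
    expect_lt(lppd1, lppd0)
  }
})

test_that("a species missing from the correlation matrix is an error", {
  ds <- make_test_dataset(seed = 111, n_per = 5)
  R <- phylo_correlation(ds$tree)[1:7, 1:7]
  expect_error(fit_varying_effects(ds, R = R, chains = 2, iter = 200),
               "missing from correlation")
})

test_that("without a true scaling effect the WAIC difference stays small", {
  n_rep <- 40
  dw <- numeric(n_rep)
  # no scaling effect at all: zero grand slope and zero slope variation
  for (r in seq_len(n_rep)) {
    ds <- make_test_dataset(seed = 900 + r, beta_bar = 0,
                            sds = c(0.1, 0.1, 0, 0))
    f1 <- fit_varying_effects(ds, include_bm = TRUE, chains = 2, iter = 800,
                              seed = 40000 + r)
    f0 <- fit_varying_effects(ds, include_bm = FALSE, chains = 2, iter = 800,
                              seed = 41000 + r)
    dw[r] <- abs(compare_models(f1, f0)$delta_waic)
  }
  expect_lt(mean(dw), 5)
})
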