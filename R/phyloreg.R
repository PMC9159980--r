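#' Fit the Bayesian phylogenetic varying-effects regression
#'
#' Individual-level model of a log morpho-functional index on centered log
#' body mass, with species-varying intercepts and slopes each split into a
#' phylogenetic component (multivariate normal with the Brownian-motion
#' correlation of the tree) and an independent species component:
#'
#' \deqn{y_i \sim N(\mu_i, \sigma), \quad
#'   \mu_i = (\bar\alpha + a_{phy,s(i)} + a_{sp,s(i)}) +
#'           (\bar\beta + b_{phy,s(i)} + b_{sp,s(i)}) x_i}
#'
#' with \eqn{a_{phy} \sim MVN(0, \sigma_{a,phy}^2 R)}, \eqn{a_{sp,s} \sim
#' N(0, \sigma_{a,sp})} and likewise for slopes. Priors: grand intercept
#' normal(mean of y, 1); grand slope normal(0, 1); the residual sd and all
#' four variance-component sds exponential(1). Partial pooling shrinks each
#' species' line toward the population line.
#'
#' Posterior draws come from a blocked Gibbs sampler operating on the
#' non-centered parameterization (effects = sd x Cholesky(R) x standard
#' normals): all location parameters are updated jointly from their
#' conditional multivariate normal, the four component sds from
#' zero-truncated-normal conditionals (they enter the mean linearly under
#' non-centering), and the residual sd by slice sampling. Four chains are run
#' by default and split-chain R-hat and effective sample sizes are computed
#' for every parameter.
#'
#' @param data A `regression_dataset` from [build_dataset()], or any list with
#'   `$data` (tibble with `y`, `x`, `species_idx`), `$species`, `$tree`.
#' @param include_bm Include the body-mass slope terms? `FALSE` fits the
#'   intercept-only model (varying intercepts retained), the comparison model
#'   for WAIC.
#' @param chains Number of MCMC chains (>= 2; default 4).
#' @param iter Iterations per chain (default 5000).
#' @param warmup Warm-up fraction in (0,1) (default 0.5).
#' @param seed Integer seed; chains use derived subseeds.
#' @param R Optional species correlation matrix; defaults to
#'   [phylo_correlation()] of the dataset's tree at unit height. Use
#'   `diag(S)` for a non-phylogenetic fit.
#' @return Object of class `phylo_regression`: `draws` (tibble, one row per
#'   kept draw with `.chain`/`.iteration` plus all parameters, including the
#'   derived per-species effects), `loglik` (kept draws x observations
#'   pointwise log-likelihood matrix), and the fit configuration.
#' @export
fit_varying_effects <- function(data, include_bm = TRUE, chains = 4,
                                iter = 5000, warmup = 0.5, seed = 1,
                                R = NULL) {
  if (chains < 2) abort("at least 2 chains are required for split-chain diagnostics")
  if (warmup <= 0 || warmup >= 1) abort("warmup fraction must be in (0, 1)")
  d <- data$data
  species <- data$species
  S <- length(species)
  n <- nrow(d)
  if (S < 2) abort("need at least 2 species")
  if (n < S) abort("need at least as many observations as species")
  if (anyNA(d$y) || anyNA(d$x)) abort("missing y or x in dataset")
  if (is.null(R)) {
    tr <- data$tree
    if (abs(tree_height(tr) - 1) > 1e-6) tr <- to_unit_height(tr)
    R <- phylo_correlation(tr, species)
  }
  if (!all(species %in% rownames(R))) {
    abort(paste0("species missing from correlation matrix: ",
                 paste(setdiff(species, rownames(R)), collapse = ", ")))
  }
  R <- R[species, species, drop = FALSE]
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("correlation matrix is not positive semi-definite")
  Lc <- tryCatch(t(chol(R)), error = function(e) {
    e2 <- eigen(R, symmetric = TRUE)
    e2$vectors %*% diag(sqrt(pmax(e2$values, 0)), S)
  })
  y <- d$y
  x <- d$x
  m_alpha <- mean(y)
  n_warm <- floor(iter * warmup)
  n_scales <- if (include_bm) 4L else 2L
  p_loc <- if (include_bm) 2L + 4L * S else 1L + 2L * S

  ols_sigma <- tryCatch(
    summary(lm(y ~ x))$sigma,
    error = function(e) sd(y)
  )
  chain_out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    chain_out[[ch]] <- with_seed(spawn_seed(seed, paste0("chain", ch)), {
      init <- list(
        theta = c(m_alpha + rnorm(1, 0, 0.3),
                  if (include_bm) rnorm(1, 0, 0.3),
                  rnorm(p_loc - 1L - include_bm, 0, 0.3)),
        scales = rexp(n_scales, 2),
        sigma = max(ols_sigma, 1e-3) * exp(runif(1, -0.5, 0.5))
      )
      .gibbs_chain(y, x, as.integer(d$species_idx), Lc, include_bm,
                   m_alpha, as.integer(iter), as.integer(n_warm), 1L, init)
    })
  }
  kept <- nrow(chain_out[[1]]$draws)
  scale_names <- if (include_bm) {
    c("sigma_a_phy", "sigma_a_sp", "sigma_b_phy", "sigma_b_sp")
  } else c("sigma_a_phy", "sigma_a_sp")
  u_names <- c(
    paste0("z_a_phy[", species, "]"), paste0("z_a_sp[", species, "]"),
    if (include_bm) c(paste0("z_b_phy[", species, "]"),
                      paste0("z_b_sp[", species, "]"))
  )
  loc_names <- c("alpha_bar", if (include_bm) "beta_bar", u_names)
  draws_list <- lapply(seq_len(chains), function(ch) {
    m <- chain_out[[ch]]$draws
    colnames(m) <- c(loc_names, scale_names, "sigma")
    dd <- tibble::as_tibble(m)
    # derived species effects on the natural scale
    u1 <- m[, paste0("z_a_phy[", species, "]"), drop = FALSE]
    u2 <- m[, paste0("z_a_sp[", species, "]"), drop = FALSE]
    aphy <- (u1 %*% t(Lc)) * m[, "sigma_a_phy"]
    asp <- u2 * m[, "sigma_a_sp"]
    colnames(aphy) <- paste0("a_phy[", species, "]")
    colnames(asp) <- paste0("a_sp[", species, "]")
    dd <- dplyr::bind_cols(dd, tibble::as_tibble(aphy), tibble::as_tibble(asp))
    if (include_bm) {
      u3 <- m[, paste0("z_b_phy[", species, "]"), drop = FALSE]
      u4 <- m[, paste0("z_b_sp[", species, "]"), drop = FALSE]
      bphy <- (u3 %*% t(Lc)) * m[, "sigma_b_phy"]
      bsp <- u4 * m[, "sigma_b_sp"]
      colnames(bphy) <- paste0("b_phy[", species, "]")
      colnames(bsp) <- paste0("b_sp[", species, "]")
      dd <- dplyr::bind_cols(dd, tibble::as_tibble(bphy), tibble::as_tibble(bsp))
    }
    dd$.chain <- ch
    dd$.iteration <- seq_len(kept)
    dd
  })
  draws <- dplyr::bind_rows(draws_list)
  loglik <- do.call(rbind, lapply(chain_out, `[[`, "loglik"))
  structure(
    list(draws = draws, loglik = loglik, data = data,
         include_bm = include_bm, chains = chains, iter = iter,
         warmup = warmup, seed = seed, R = R, species = species,
         n = n, kept_per_chain = kept),
    class = "phylo_regression"
  )
}

#' @export
print.phylo_regression <- function(x, ...) {
  cat(sprintf(
    "<phylo_regression> %s model: %d obs, %d species, %d chains x %d kept draws (seed %d)\n",
    if (x$include_bm) "body-mass" else "intercept-only",
    x$n, length(x$species), x$chains, x$kept_per_chain, x$seed))
  core <- c("alpha_bar", if (x$include_bm) "beta_bar", "sigma",
            "sigma_a_phy", "sigma_a_sp",
            if (x$include_bm) c("sigma_b_phy", "sigma_b_sp"))
  print(posterior_summary(x, pars = core), n = length(core))
  invisible(x)
}

#' @keywords internal
#' Split each chain in half and return a (length x n_split_chains) matrix.
split_chains <- function(mat_by_chain) {
  half <- floor(nrow(mat_by_chain[[1]]) / 2)
  do.call(cbind, lapply(mat_by_chain, function(m) {
    cbind(m[seq_len(half), , drop = FALSE],
          m[seq.int(nrow(m) - half + 1, nrow(m)), , drop = FALSE])
  }))
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Gelman-Rubin diagnostic on split chains: each chain is halved, so trends
#' within a chain inflate the statistic as well as disagreement across chains.
#'
#' @param x Matrix of draws, iterations x chains (>= 2 columns after
#'   splitting), or numeric vector with `chains` attribute.
#' @return Scalar R-hat (1 = converged).
#' @export
split_rhat <- function(x) {
  m <- ncol(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  W <- mean(apply(x, 2, var))
  B <- n * var(colMeans(x))
  if (W == 0) return(1)
  varplus <- (n - 1) / n * W + B / n
  sqrt(varplus / W)
}

#' @keywords internal
#' Effective sample size over split chains (Geyer initial-monotone sum of
#' autocorrelations).
ess_split <- function(x) {
  m <- ncol(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  W <- mean(apply(x, 2, var))
  if (W == 0) return(NA_real_)
  B <- n * var(colMeans(x))
  varplus <- (n - 1) / n * W + B / n
  max_lag <- n - 1
  acov <- sapply(seq_len(m), function(j) {
    stats::acf(x[, j], lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  rho <- 1 - (W - rowMeans(acov)) / varplus  # rho[1] is lag 0 (= ~1)
  tau <- 0
  t <- 1
  prev_pair <- Inf
  while (t + 1 <= length(rho) - 1) {
    pair <- rho[t + 1] + rho[t + 2]
    if (pair < 0) break
    pair <- min(pair, prev_pair)  # initial monotone
    tau <- tau + pair
    prev_pair <- pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * tau)
  min(ess, m * n)
}

#' Posterior summary table with compatibility intervals and diagnostics
#'
#' Per parameter: posterior mean, sd, central percentile interval at the
#' requested mass (default 0.89), split-chain R-hat and effective sample
#' size. A `converged` flag marks R-hat <= 1.05.
#'
#' @param fit A `phylo_regression` object (or a draws tibble with
#'   `.chain`/`.iteration` columns).
#' @param prob Interval mass (default 0.89).
#' @param pars Parameters to include (default: all).
#' @return Tibble: `term`, `estimate` (mean), `std.error` (sd), `conf.low`,
#'   `conf.high`, `rhat`, `ess`, `converged`.
#' @export
posterior_summary <- function(fit, prob = 0.89, pars = NULL) {
  draws <- if (inherits(fit, "phylo_regression")) fit$draws else tibble::as_tibble(fit)
  if (!all(c(".chain", ".iteration") %in% names(draws))) {
    abort("draws must carry .chain and .iteration columns")
  }
  if (length(unique(draws$.chain)) < 2) abort("need >= 2 chains")
  pnames <- setdiff(names(draws), c(".chain", ".iteration"))
  if (!is.null(pars)) pnames <- intersect(pars, pnames)
  qlo <- (1 - prob) / 2
  qhi <- 1 - qlo
  by_chain <- split(draws[pnames], draws$.chain)
  rows <- lapply(pnames, function(p) {
    v <- draws[[p]]
    mats <- split_chains(lapply(by_chain, function(d) as.matrix(d[p])))
    rh <- split_rhat(mats)
    tibble::tibble(
      term = p, estimate = mean(v), std.error = sd(v),
      conf.low = unname(quantile(v, qlo)), conf.high = unname(quantile(v, qhi)),
      rhat = rh, ess = ess_split(mats),
      converged = is.na(rh) | rh <= 1.05
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
tidy.phylo_regression <- function(x, prob = 0.89, pars = NULL, ...) {
  if (is.null(pars)) {
    pars <- c("alpha_bar", if (x$include_bm) "beta_bar", "sigma",
              "sigma_a_phy", "sigma_a_sp",
              if (x$include_bm) c("sigma_b_phy", "sigma_b_sp"),
              grep("^[ab]_(phy|sp)\\[", names(x$draws), value = TRUE))
  }
  posterior_summary(x, prob = prob, pars = pars)
}

#' @export
glance.phylo_regression <- function(x, ...) {
  w <- compute_waic(x)
  core <- posterior_summary(
    x, pars = c("alpha_bar", if (x$include_bm) "beta_bar", "sigma"))
  tibble::tibble(
    n = x$n, n_species = length(x$species),
    waic = w$waic, p_waic = w$p_waic, lppd = w$lppd,
    max_rhat = max(core$rhat, na.rm = TRUE),
    include_bm = x$include_bm
  )
}

#' Widely applicable information criterion
#'
#' From the pointwise log-likelihood matrix: `lppd = sum_i log mean_draws
#' p(y_i | draw)`, effective parameters `p_waic = sum_i var_draws log p(y_i |
#' draw)`, and `WAIC = -2 (lppd - p_waic)` on the deviance scale.
#'
#' @param fit A `phylo_regression` object, or a draws x observations
#'   pointwise log-likelihood matrix.
#' @return Object of class `waic_result`: list with `lppd`, `p_waic`, `waic`,
#'   `n`, and `pointwise` tibble (`lppd_i`, `p_i`, `waic_i`).
#' @export
compute_waic <- function(fit) {
  ll <- if (inherits(fit, "phylo_regression")) fit$loglik else as.matrix(fit)
  if (nrow(ll) < 2) abort("need at least 2 posterior draws")
  lppd_i <- apply(ll, 2, function(v) {
    m <- max(v)
    m + log(mean(exp(v - m)))
  })
  p_i <- apply(ll, 2, var)
  waic_i <- -2 * (lppd_i - p_i)
  structure(
    list(lppd = sum(lppd_i), p_waic = sum(p_i), waic = sum(waic_i),
         n = ncol(ll),
         pointwise = tibble::tibble(lppd_i = lppd_i, p_i = p_i,
                                    waic_i = waic_i)),
    class = "waic_result"
  )
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC %.2f  (lppd %.2f, p_waic %.2f, n = %d)\n",
              x$waic, x$lppd, x$p_waic, x$n))
  invisible(x)
}

#' Compare two models by WAIC
#'
#' Difference in WAIC between the worse and the better model, with the
#' standard error of the pointwise differences, `sqrt(n * var(waic_i^A -
#' waic_i^B))` — the scale on which a difference should be judged.
#'
#' @param full,reduced `waic_result` objects (or `phylo_regression` fits) on
#'   the same observations in the same order.
#' @param labels Length-2 labels for reporting (default `"full"`,
#'   `"reduced"`).
#' @return Object of class `waic_comparison`: tibble with one row
#'   (`preferred`, `delta_waic` >= 0, `delta_se`, `waic_full`,
#'   `waic_reduced`).
#' @export
compare_models <- function(full, reduced, labels = c("full", "reduced")) {
  if (inherits(full, "phylo_regression")) full <- compute_waic(full)
  if (inherits(reduced, "phylo_regression")) reduced <- compute_waic(reduced)
  if (full$n != reduced$n) abort("models were fitted to different numbers of observations")
  d <- full$pointwise$waic_i - reduced$pointwise$waic_i
  delta <- abs(full$waic - reduced$waic)
  dse <- sqrt(full$n * var(d))
  if (full$n == 1 || var(d) == 0) dse <- 0
  out <- tibble::tibble(
    preferred = if (full$waic <= reduced$waic) labels[1] else labels[2],
    delta_waic = delta, delta_se = dse,
    waic_full = full$waic, waic_reduced = reduced$waic, n = full$n
  )
  class(out) <- c("waic_comparison", class(out))
  out
}

#' Phylogenetic vs species-specific variance attribution
#'
#' Per posterior draw, the phylogenetic share of the between-species variance
#' of intercepts is `sigma_a_phy^2 / (sigma_a_phy^2 + sigma_a_sp^2)`, and
#' analogously for slopes. Reported as posterior mean with a compatibility
#' interval; draws where both components are exactly zero are skipped and
#' counted.
#'
#' @param fit A `phylo_regression` fit.
#' @param prob Interval mass (default 0.89).
#' @return Tibble: `component` (`"intercept"`, and `"slope"` when present),
#'   `phylo_share` (posterior mean), `conf.low`, `conf.high`, `n_skipped`.
#' @export
variance_shares <- function(fit, prob = 0.89) {
  stopifnot(inherits(fit, "phylo_regression"))
  qlo <- (1 - prob) / 2
  one <- function(sp, ss, label) {
    tot <- sp^2 + ss^2
    keep <- tot > 0
    share <- sp[keep]^2 / tot[keep]
    tibble::tibble(
      component = label, phylo_share = mean(share),
      conf.low = unname(quantile(share, qlo)),
      conf.high = unname(quantile(share, 1 - qlo)),
      n_skipped = sum(!keep)
    )
  }
  out <- one(fit$draws$sigma_a_phy, fit$draws$sigma_a_sp, "intercept")
  if (fit$include_bm) {
    out <- dplyr::bind_rows(
      out, one(fit$draws$sigma_b_phy, fit$draws$sigma_b_sp, "slope"))
  }
  out
}

#' @export
autoplot.phylo_regression <- function(object, prob = 0.89, n_grid = 50, ...) {
  d <- object$data$data
  xg <- seq(min(d$x), max(d$x), length.out = n_grid)
  a <- object$draws$alpha_bar
  b <- if (object$include_bm) object$draws$beta_bar else rep(0, length(a))
  mu <- outer(a, rep(1, n_grid)) + outer(b, xg)
  qlo <- (1 - prob) / 2
  band <- tibble::tibble(
    x = xg,
    fit = colMeans(mu),
    lo = apply(mu, 2, quantile, qlo),
    hi = apply(mu, 2, quantile, 1 - qlo)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$x, ymin = .data$lo,
                                      ymax = .data$hi),
                         inherit.aes = FALSE, alpha = 0.3) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(x = .data$x, y = .data$fit),
                       inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$species), size = 1) +
    ggplot2::labs(
      x = "centered log body mass (g)",
      y = paste0("log ", object$data$index),
      colour = "species",
      subtitle = sprintf("population line with %d%% compatibility band",
                         round(100 * prob))
    ) +
    ggplot2::theme_minimal()
}
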