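test_that("transition matrices are proper stochastic matrices", {
  Q <- mk_er_matrix(0.5)
  for (t_br in c(0, 0.01, 0.5, 3, 50)) {
    P <- mk_transition_matrix(Q, t_br)
    expect_equal(rowSums(P), c(absent = 1, present = 1), tolerance = 1e-10)
    expect_true(all(P >= 0))
    expect_equal(P, as.matrix(Matrix::expm(Q * t_br)), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # asymmetric 3-state generator against the numerical exponential
  Q3 <- matrix(c(-3, 1, 2, 0.5, -1, 0.5, 1, 1, -2), 3, 3, byrow = TRUE)
  rownames(Q3) <- colnames(Q3) <- c("a", "b", "c")
  expect_equal(mk_transition_matrix(Q3, 0.7),
               as.matrix(Matrix::expm(Q3 * 0.7)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("pruning likelihood handles zero-rate and impossible data", {
  tt <- parse_newick("(A:1,B:1);")
  Q0 <- mk_er_matrix(0, c("0", "1"))
  expect_equal(mk_loglik(tt, c(A = "0", B = "0"), Q0), log(0.5),
               tolerance = 1e-12, ignore_attr = TRUE)
  ll <- mk_loglik(tt, c(A = "0", B = "1"), Q0)
  expect_identical(as.numeric(ll), -Inf)
  expect_true(attr(ll, "impossible"))
})

test_that("pruning likelihood matches the closed form on the two-tip ER case", {
  # q = 0.5, both branches length 1, both tips state 0, prior (1/2, 1/2):
  # L = (p00^2 + p10^2) / 2 with p00 = (1 + e^(-2q))/2
  tt <- parse_newick("(A:1,B:1);")
  q <- 0.5
  p00 <- (1 + exp(-2 * q)) / 2
  p10 <- (1 - exp(-2 * q)) / 2
  expect_equal(
    mk_loglik(tt, c(A = "0", B = "0"), mk_er_matrix(q, c("0", "1"))),
    log(0.5 * (p00^2 + p10^2)),  # = -1.2593656...
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("pruning equals exhaustive enumeration on random small trees", {
  set.seed(202)
  for (case in 1:40) {
    n <- sample(3:5, 1)
    tr <- simulate_yule_tree(n, seed = 300 + case)
    tips <- random_binary_states(tr$tip.label)
    q01 <- runif(1, 0.1, 3)
    q10 <- runif(1, 0.1, 3)
    Q <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE,
                dimnames = list(c("0", "1"), c("0", "1")))
    prior <- c(0.5, 0.5)
    expect_equal(as.numeric(mk_loglik(tr, tips, Q, prior)),
                 log(bruteforce_mk_lik(tr, tips, Q, prior)),
                 tolerance = 1e-9)
  }
})

test_that("likelihood is invariant under consistent state relabeling", {
  tr <- simulate_yule_tree(6, seed = 17)
  tips <- random_binary_states(tr$tip.label)
  Q <- matrix(c(-1.2, 1.2, 0.4, -0.4), 2, 2, byrow = TRUE,
              dimnames = list(c("0", "1"), c("0", "1")))
  relab <- c(`0` = "x", `1` = "y")
  Q2 <- Q[2:1, 2:1]
  rownames(Q2) <- colnames(Q2) <- relab[rownames(Q)[2:1]]
  tips2 <- setNames(relab[tips], names(tips))
  expect_equal(as.numeric(mk_loglik(tr, tips, Q)),
               as.numeric(mk_loglik(tr, tips2, Q2)), tolerance = 1e-12)
})

test_that("ER fit warns at the boundary for constant characters", {
  tr <- simulate_yule_tree(6, seed = 23)
  tips <- setNames(rep("present", 6), tr$tip.label)
  expect_warning(fit <- fit_mk(tr, tips, states = c("absent", "present")),
                 "constant")
  expect_true(fit$boundary)
  expect_equal(fit$rates, 1e-8)
})

test_that("ML rate maximizes the likelihood and is consistent on large trees", {
  meds <- numeric(12)
  for (r in seq_along(meds)) {
    tr <- simulate_yule_tree(200, seed = 400 + r)
    h <- simulate_mk_character(tr, mk_er_matrix(1, c("0", "1")), seed = 500 + r)
    if (length(unique(h$states)) < 2) { meds[r] <- NA; next }
    fit <- fit_mk(tr, h$states, model = "ER")
    meds[r] <- fit$rates[1]
    expect_gte(fit$loglik + 1e-6,
               as.numeric(mk_loglik(tr, h$states, mk_er_matrix(1, c("0", "1")))))
  }
  expect_gt(median(meds, na.rm = TRUE), 0.6)
  expect_lt(median(meds, na.rm = TRUE), 1.5)
})

test_that("ML estimates agree with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_yule_tree(12, seed = 31)
  h <- simulate_mk_character(tr, mk_er_matrix(1.5, c("0", "1")), seed = 32)
  skip_if(length(unique(h$states)) < 2)
  ours <- fit_mk(tr, h$states, model = "ER")
  theirs <- phytools::fitMk(tr, h$states, model = "ER", pi = "equal")
  expect_equal(as.numeric(ours$loglik), as.numeric(stats::logLik(theirs)),
               tolerance = 1e-4)
  expect_equal(ours$rates[1], theirs$rates[1], tolerance = 1e-3)
})

test_that("marginal posteriors: limits, symmetry, and exhaustive oracle", {
  tr <- simulate_yule_tree(6, seed = 41)
  tips1 <- setNames(rep("1", 6), tr$tip.label)
  mp <- marginal_node_posteriors(tr, tips1, mk_er_matrix(1e-8, c("0", "1")))
  expect_true(all(mp$`1`[7:11] > 0.999))

  tt <- parse_newick("(A:1,B:1);")
  mp2 <- marginal_node_posteriors(tt, c(A = "0", B = "1"),
                                  mk_er_matrix(0.8, c("0", "1")))
  expect_equal(mp2$`0`[mp2$clade == "A|B"], 0.5, tolerance = 1e-12)

  for (case in 1:10) {
    tr4 <- simulate_yule_tree(4, seed = 600 + case)
    tips <- random_binary_states(tr4$tip.label)
    Q <- mk_er_matrix(runif(1, 0.2, 2), c("0", "1"))
    mp4 <- marginal_node_posteriors(tr4, tips, Q)
    oracle <- bruteforce_mk_marginals(tr4, tips, Q, c(0.5, 0.5))
    ours <- as.matrix(mp4[mp4$node > 4, c("0", "1")])
    expect_equal(unname(ours), unname(oracle), tolerance = 1e-9)
  }
})

test_that("ARD fitting nests ER and handles unknown tip states", {
  tr <- simulate_yule_tree(15, seed = 61)
  Qtrue <- matrix(c(-2, 2, 0.3, -0.3), 2, 2, byrow = TRUE,
                  dimnames = list(c("0", "1"), c("0", "1")))
  h <- simulate_mk_character(tr, Qtrue, seed = 62)
  skip_if(length(unique(h$states)) < 2)
  er <- fit_mk(tr, h$states, model = "ER")
  ard <- fit_mk(tr, h$states, model = "ARD")
  # ER is a constrained ARD: the richer model cannot fit worse
  expect_gte(ard$loglik, er$loglik - 1e-6)
  expect_equal(rowSums(ard$Q), c(`0` = 0, `1` = 0), tolerance = 1e-12)

  # an unknown tip contributes a uniform partial likelihood: the likelihood
  # must equal the sum over that tip's possible states of the full data
  tips_unknown <- h$states
  tips_unknown[1] <- "unknown"
  l_marginal <- exp(as.numeric(mk_loglik(tr, tips_unknown, er$Q)))
  l_sum <- 0
  for (s in c("0", "1")) {
    tips_s <- h$states
    tips_s[1] <- s
    l_sum <- l_sum + exp(as.numeric(mk_loglik(tr, tips_s, er$Q)))
  }
  expect_equal(l_marginal, l_sum, tolerance = 1e-10)
})
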