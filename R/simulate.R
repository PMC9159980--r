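#' Run code with a temporarily seeded RNG stream
#'
#' All generators in the package are pure functions of (parameters, seed): the
#' global RNG state is saved, seeded, and restored afterwards.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a bounded child seed from a parent seed and a stage label
#'
#' Deterministic substream spawning: one global seed reproducibly seeds every
#' pipeline stage. Result is always in [0, 2^31 - 1].
#' @keywords internal
spawn_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Simulate a pure-birth (Yule) ultrametric tree scaled to unit height
#'
#' A stand-in for a time-calibrated posterior tree: only the Brownian
#' correlation structure matters to the stages tested against it.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed.
#' @param birth Speciation rate before rescaling (default 1; the post-hoc
#'   unit-height scaling makes it irrelevant to downstream use).
#' @param taxa Optional tip labels (default `t1..tn`).
#' @return Ultrametric `phylo` of height 1.
#' @export
simulate_yule_tree <- function(n_taxa, seed, birth = 1, taxa = NULL) {
  if (n_taxa < 2) abort("n_taxa must be >= 2")
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = birth, death = 0))
  if (!is.null(taxa)) {
    stopifnot(length(taxa) == n_taxa)
    tr$tip.label <- taxa
  }
  to_unit_height(tr)
}

#' @keywords internal
mvn_from_correlation <- function(n_draws, sd, R) {
  # matrix square root via symmetric eigendecomposition; tolerates the
  # semi-definite case (zero-length shared branches)
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  A <- e$vectors %*% (sqrt(vals) * t(e$vectors))
  z <- matrix(rnorm(n_draws * nrow(R)), nrow(R), n_draws)
  t(sd * (A %*% z))
}

#' Simulate species-level varying intercepts and slopes on a tree
#'
#' Species effects are the sum of a phylogenetic component, drawn from a
#' zero-mean multivariate normal with covariance `sd^2 *`
#' [phylo_correlation()], and an independent species component, drawn i.i.d.
#' normal — the generating side of the varying-effects regression model.
#'
#' @param tree Ultrametric `phylo`.
#' @param alpha_bar,beta_bar Grand intercept and grand slope.
#' @param sigma_a_phy,sigma_a_sp Scales of the phylogenetic and independent
#'   intercept deviations.
#' @param sigma_b_phy,sigma_b_sp Likewise for slopes.
#' @param seed Integer seed.
#' @return Object of class `species_effects`: tibble with one row per tip
#'   (`species`, `a_phy`, `a_sp`, `b_phy`, `b_sp`, `intercept`, `slope`) plus
#'   attributes `truth` (the generating parameters) and `tree`.
#' @export
simulate_varying_effects <- function(tree, alpha_bar, beta_bar,
                                     sigma_a_phy, sigma_a_sp,
                                     sigma_b_phy, sigma_b_sp, seed) {
  stopifnot(sigma_a_phy >= 0, sigma_a_sp >= 0, sigma_b_phy >= 0, sigma_b_sp >= 0)
  tree <- validate_tree(tree)
  R <- phylo_correlation(tree)
  S <- nrow(R)
  eff <- with_seed(seed, {
    a_phy <- drop(mvn_from_correlation(1, sigma_a_phy, R))
    b_phy <- drop(mvn_from_correlation(1, sigma_b_phy, R))
    a_sp <- rnorm(S, 0, sigma_a_sp)
    b_sp <- rnorm(S, 0, sigma_b_sp)
    tibble::tibble(
      species = tree$tip.label,
      a_phy = a_phy, a_sp = a_sp, b_phy = b_phy, b_sp = b_sp,
      intercept = alpha_bar + a_phy + a_sp,
      slope = beta_bar + b_phy + b_sp
    )
  })
  attr(eff, "truth") <- list(
    alpha_bar = alpha_bar, beta_bar = beta_bar,
    sigma_a_phy = sigma_a_phy, sigma_a_sp = sigma_a_sp,
    sigma_b_phy = sigma_b_phy, sigma_b_sp = sigma_b_sp, seed = seed
  )
  attr(eff, "tree") <- tree
  class(eff) <- c("species_effects", class(eff))
  eff
}

#' Simulate an individual-level index-measurement table
#'
#' For each individual of species s: log body mass `x ~ N(bm_log_mean[s],
#' bm_log_sd[s])`, log index `y = intercept[s] + slope[s] * (x - center) +
#' N(0, sigma)` where `center` is the realized mean log body mass over the
#' retained (non-absent) rows — the same origin [build_dataset()] uses. Records
#' are emitted on the natural scale (`value = exp(y)` percent,
#' `body_mass_g = exp(x)`).
#'
#' @param effects A `species_effects` object from [simulate_varying_effects()].
#' @param n_per_species Integer count per species, recycled over species.
#' @param bm_log_mean,bm_log_sd Per-species mean and sd of log body mass
#'   (natural log grams), recycled.
#' @param sigma Residual sd of log index around the species line.
#' @param seed Integer seed.
#' @param index Index label stamped on the records (default `"IFA"`).
#' @param absent_species Character vector of species whose superstructure is
#'   absent: their rows get `value = NA` (the naked-mole-rat analog). Default
#'   none.
#' @return Tibble of index records (as [compute_indices()] emits) with
#'   attribute `truth` extended by `sigma`, `center_log_bm` and the seed.
#' @export
simulate_measurements <- function(effects, n_per_species, bm_log_mean,
                                  bm_log_sd = 0.2, sigma = 0.1, seed = 1,
                                  index = "IFA", absent_species = character()) {
  stopifnot(inherits(effects, "species_effects"), sigma >= 0, all(n_per_species >= 1))
  S <- nrow(effects)
  n_per_species <- rep_len(as.integer(n_per_species), S)
  bm_log_mean <- rep_len(bm_log_mean, S)
  bm_log_sd <- rep_len(bm_log_sd, S)
  s_idx <- rep(seq_len(S), n_per_species)
  n <- length(s_idx)
  absent <- effects$species[s_idx] %in% absent_species
  rec <- with_seed(seed, {
    x <- rnorm(n, bm_log_mean[s_idx], bm_log_sd[s_idx])
    center <- mean(x[!absent])
    y <- effects$intercept[s_idx] + effects$slope[s_idx] * (x - center) +
      rnorm(n, 0, sigma)
    tibble::tibble(
      specimen_id = sprintf("sim%04d", seq_len(n)),
      species = effects$species[s_idx],
      index = index,
      value = ifelse(absent, NA_real_, exp(y)),
      body_mass_g = exp(x),
      center = center
    )
  })
  truth <- attr(effects, "truth")
  truth$sigma <- sigma
  truth$measurement_seed <- seed
  truth$center_log_bm <- rec$center[1]
  rec$center <- NULL
  attr(rec, "truth") <- truth
  attr(rec, "effects") <- effects
  rec
}

#' Validate a continuous-time Markov generator matrix
#' @keywords internal
validate_generator <- function(Q, tol = 1e-8) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) abort("Q must be a square matrix")
  off <- Q
  diag(off) <- 0
  if (any(off < -tol)) abort("Q off-diagonal rates must be >= 0")
  if (any(abs(rowSums(Q)) > tol * max(1, max(abs(Q))))) {
    abort("Q rows must sum to 0")
  }
  if (is.null(rownames(Q))) {
    rownames(Q) <- colnames(Q) <- as.character(seq_len(nrow(Q)) - 1L)
  }
  Q
}

#' Equal-rates binary generator matrix
#'
#' @param rate Transition rate per unit branch length.
#' @param states State labels (default `"absent"`, `"present"`).
#' @return 2x2 generator matrix.
#' @export
mk_er_matrix <- function(rate, states = c("absent", "present")) {
  k <- length(states)
  Q <- matrix(rate, k, k, dimnames = list(states, states))
  diag(Q) <- -rate * (k - 1)
  Q
}

#' Simulate a discrete character along a tree under the Mk model
#'
#' States evolve root-to-tips as a continuous-time Markov chain with generator
#' `Q`: along each branch, exponential waiting times between state changes.
#' The full event history is retained as ground truth for testing the
#' character-map sampler.
#'
#' @param tree `phylo` with branch lengths. Polytomies are allowed.
#' @param Q Generator matrix (rows sum to 0, off-diagonals >= 0), with state
#'   labels as dimnames.
#' @param seed Integer seed.
#' @param root_state Fixed root state label, or `NULL` to draw from
#'   `root_prior`.
#' @param root_prior Probability vector over states (default uniform), used
#'   when `root_state` is `NULL`.
#' @return Object of class `character_history`: list with `tree`, `states`
#'   (named character vector over tips), `node_states` (states at every node,
#'   indexed by ape node number), and `events` (tibble: `edge`, `parent`,
#'   `child`, `time` from branch start, `to_state`).
#' @export
simulate_mk_character <- function(tree, Q, seed, root_state = NULL,
                                  root_prior = NULL) {
  tree <- validate_tree(tree)
  Q <- validate_generator(Q)
  states <- rownames(Q)
  k <- length(states)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  nnode <- ape::Ntip(tree) + tree$Nnode
  root <- ape::Ntip(tree) + 1L
  with_seed(seed, {
    node_state <- integer(nnode)
    node_state[root] <- if (is.null(root_state)) {
      sample.int(k, 1, prob = root_prior)
    } else {
      m <- match(root_state, states)
      if (is.na(m)) abort("root_state not among Q's state labels")
      m
    }
    ord <- ape::reorder.phylo(tree, "cladewise")
    ev <- list()
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]
      chi <- ord$edge[e, 2]
      len <- ord$edge.length[e]
      s <- node_state[par]
      t_now <- 0
      while (TRUE) {
        rate_out <- -Q[s, s]
        if (rate_out <= 0) break
        t_now <- t_now + rexp(1, rate_out)
        if (t_now >= len) break
        probs <- Q[s, ]
        probs[s] <- 0
        s <- sample.int(k, 1, prob = probs)
        ev[[length(ev) + 1L]] <- list(edge = e, parent = par, child = chi,
                                      time = t_now, to_state = states[s])
      }
      node_state[chi] <- s
    }
    events <- if (length(ev) > 0L) {
      dplyr::bind_rows(lapply(ev, tibble::as_tibble))
    } else {
      tibble::tibble(edge = integer(), parent = integer(), child = integer(),
                     time = numeric(), to_state = character())
    }
    structure(
      list(
        tree = ord,
        states = setNames(states[node_state[seq_len(ape::Ntip(tree))]],
                          ord$tip.label),
        node_states = states[node_state],
        events = events
      ),
      class = "character_history"
    )
  })
}

#' @export
print.character_history <- function(x, ...) {
  cat(sprintf("<character_history> %d tips, %d state-change events\n",
              ape::Ntip(x$tree), nrow(x$events)))
  print(table(x$states))
  invisible(x)
}
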