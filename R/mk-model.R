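#' Transition probability matrix of a continuous-time Markov chain
#'
#' `exp(Q t)` for a generator `Q`. The 2-state case uses the closed form; the
#' general case an eigendecomposition (symmetric fast path), falling back to
#' [Matrix::expm()] for defective generators.
#'
#' @param Q Generator matrix.
#' @param t Elapsed time (branch length), `>= 0`.
#' @return Stochastic matrix of the same dimension as `Q`.
#' @export
mk_transition_matrix <- function(Q, t) {
  stopifnot(t >= 0)
  k <- nrow(Q)
  if (k == 2L) {
    a <- Q[1, 2]
    b <- Q[2, 1]
    r <- a + b
    if (r <= 0) {
      P <- diag(2)
    } else {
      e <- exp(-r * t)
      P <- rbind(
        c(b + a * e, a - a * e),
        c(b - b * e, a + b * e)
      ) / r
    }
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  if (isTRUE(all.equal(Q, t(Q), tolerance = 1e-12))) {
    e <- eigen(Q, symmetric = TRUE)
    P <- e$vectors %*% (exp(e$values * t) * t(e$vectors))
  } else {
    e <- eigen(Q)
    P <- tryCatch({
      if (rcond(e$vectors) < 1e-12) stop("defective")
      Re(e$vectors %*% diag(exp(e$values * t), k) %*% solve(e$vectors))
    }, error = function(err) as.matrix(Matrix::expm(Q * t)))
  }
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Extract one character's tip states as a named vector
#'
#' @param states Data frame with columns `species`, `character`, `state` (the
#'   layout of [molerat_tip_states()]).
#' @param character Character name to extract.
#' @return Named character vector, species -> state.
#' @export
tip_state_vector <- function(states, character) {
  s <- dplyr::filter(tibble::as_tibble(states), .data$character == !!character)
  if (nrow(s) == 0L) abort(paste0("no tip states for character ", character))
  setNames(as.character(s$state), trimws(as.character(s$species)))
}

#' @keywords internal
#' Tip partial-likelihood matrix: one row per node (tips first, ape
#' numbering), one column per state. Unknown/NA tips get a row of ones.
mk_tip_partials <- function(tree, tip_states, states) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss) > 0L) {
    abort(paste0("tip state missing for: ", paste(miss, collapse = ", ")))
  }
  obs <- tip_states[tree$tip.label]
  bad <- setdiff(unique(obs[!is.na(obs) & obs != "unknown"]), states)
  if (length(bad) > 0L) {
    abort(paste0("tip state(s) not among Q's labels: ", paste(bad, collapse = ", ")))
  }
  L <- matrix(1, nnode, length(states))
  for (i in seq_len(ntip)) {
    if (!is.na(obs[i]) && obs[i] != "unknown") {
      L[i, ] <- as.numeric(states == obs[i])
    }
  }
  L
}

#' @keywords internal
#' Postorder pruning pass. Returns per-node partial likelihoods (scaled),
#' per-edge transition matrices, and the accumulated log scaling factor.
mk_prune <- function(tree, tip_states, Q, root_prior) {
  Q <- validate_generator(Q)
  states <- rownames(Q)
  k <- length(states)
  post <- ape::reorder.phylo(tree, "postorder")
  L <- mk_tip_partials(post, tip_states, states)
  nedge <- nrow(post$edge)
  Pmats <- vector("list", nedge)
  logscale <- 0
  dead <- FALSE
  for (e in seq_len(nedge)) {
    par <- post$edge[e, 1]
    chi <- post$edge[e, 2]
    P <- mk_transition_matrix(Q, post$edge.length[e])
    Pmats[[e]] <- P
    v <- as.vector(P %*% L[chi, ])
    s <- sum(v)
    if (s <= 0) { dead <- TRUE; break }
    # normalize the child message so long ladders cannot underflow
    L[par, ] <- L[par, ] * (v / s)
    logscale <- logscale + log(s)
    sp <- sum(L[par, ])
    if (sp > 0 && sp < 1e-200) {
      L[par, ] <- L[par, ] / sp
      logscale <- logscale + log(sp)
    }
  }
  list(tree = post, partials = L, Pmats = Pmats, logscale = logscale,
       states = states, k = k, dead = dead, root = ape::Ntip(post) + 1L,
       root_prior = root_prior)
}

#' Mk-model log-likelihood by Felsenstein pruning
#'
#' Log probability of the observed tip states given the tree, generator `Q`,
#' and a prior over the root state, computed by the postorder pruning
#' algorithm with per-branch transition matrices `exp(Q t)`.
#'
#' @param tree `phylo` with branch lengths.
#' @param tip_states Named character vector (taxon -> state label), or
#'   `"unknown"`/`NA` for a uniform partial likelihood.
#' @param Q Generator matrix with state labels as dimnames.
#' @param root_prior Probability vector over states: `"equal"` (default),
#'   `"stationary"`, or a numeric vector summing to 1.
#' @return Log-likelihood (scalar). `-Inf`, with attribute `impossible =
#'   TRUE`, when the data have zero probability under `Q` (e.g. a zero-rate
#'   generator with differing tip states).
#' @export
mk_loglik <- function(tree, tip_states, Q, root_prior = "equal") {
  tree <- validate_tree(tree)
  Q <- validate_generator(Q)
  prior <- resolve_root_prior(root_prior, Q)
  pr <- mk_prune(tree, tip_states, Q, prior)
  if (pr$dead) return(structure(-Inf, impossible = TRUE))
  lik <- sum(prior * pr$partials[pr$root, ])
  if (lik <= 0) return(structure(-Inf, impossible = TRUE))
  log(lik) + pr$logscale
}

#' @keywords internal
resolve_root_prior <- function(root_prior, Q) {
  k <- nrow(Q)
  if (is.character(root_prior)) {
    root_prior <- match.arg(root_prior, c("equal", "stationary"))
    if (root_prior == "equal") return(rep(1 / k, k))
    # stationary distribution: left null vector of Q
    ns <- t(Null(t(Q)))
    if (nrow(ns) == 0) return(rep(1 / k, k))
    p <- abs(ns[1, ])
    return(p / sum(p))
  }
  stopifnot(length(root_prior) == k, all(root_prior >= 0))
  if (abs(sum(root_prior) - 1) > 1e-8) abort("root_prior must sum to 1")
  root_prior
}

#' @keywords internal
Null <- function(M) {
  # orthonormal basis of the null space of t(M) x = 0, via SVD
  s <- svd(M, nu = 0, nv = ncol(M))
  tol <- max(dim(M)) * max(s$d) * .Machine$double.eps
  rank <- sum(s$d > tol)
  if (rank == ncol(M)) matrix(0, ncol(M), 0) else s$v[, (rank + 1):ncol(M), drop = FALSE]
}

#' Maximum-likelihood fit of the Mk model
#'
#' Estimates the transition-rate generator from tip states on a tree. `ER`
#' fits a single rate by bounded 1-D search on the log scale (bracket
#' `[1e-8, 100]` per unit tree height, convergence tolerance 1e-8); `ARD`
#' (binary characters) fits both rates by quasi-Newton search. A constant
#' character has its ML rate at the lower boundary; a warning is emitted and
#' the boundary estimate returned.
#'
#' @inheritParams mk_loglik
#' @param model `"ER"` (equal rates, default) or `"ARD"` (all rates differ;
#'   binary characters only).
#' @param states State labels; defaults to the sorted unique observed states
#'   (supply explicitly when some states are unobserved).
#' @return Object of class `mk_fit`: list with `Q`, `loglik`, `rates`,
#'   `model`, `states`, `root_prior`, `boundary` flag.
#' @export
fit_mk <- function(tree, tip_states, model = c("ER", "ARD"),
                   root_prior = "equal", states = NULL) {
  model <- match.arg(model)
  tree <- validate_tree(tree)
  obs <- tip_states[!is.na(tip_states) & tip_states != "unknown"]
  if (is.null(states)) states <- sort(unique(as.character(obs)))
  k <- length(states)
  if (k < 1L) abort("no observed tip states")
  if (k == 1L) states <- c(states, paste0(states, "_alt"))
  make_Q <- function(rates) {
    if (model == "ER") {
      mk_er_matrix(rates[1], states)
    } else {
      if (length(states) != 2L) abort("ARD is implemented for binary characters")
      matrix(c(-rates[1], rates[1], rates[2], -rates[2]), 2, 2, byrow = TRUE,
             dimnames = list(states, states))
    }
  }
  nll <- function(log_rates) {
    ll <- mk_loglik(tree, tip_states, make_Q(exp(log_rates)), root_prior)
    if (!is.finite(ll)) 1e10 else -ll
  }
  lo <- log(1e-8)
  hi <- log(100)
  constant <- length(unique(obs)) < 2L
  boundary <- FALSE
  if (constant) {
    warn("constant character: ML rate is at the lower boundary")
    rates <- rep(1e-8, if (model == "ER") 1L else 2L)
    boundary <- TRUE
  } else if (model == "ER") {
    op <- optimize(nll, c(lo, hi), tol = 1e-8)
    rates <- exp(op$minimum)
    boundary <- op$minimum < lo + 1e-4 || op$minimum > hi - 1e-4
  } else {
    op <- optim(c(0, 0), nll, method = "L-BFGS-B", lower = lo, upper = hi,
                control = list(factr = 1e4))
    rates <- exp(op$par)
    boundary <- any(op$par < lo + 1e-4 | op$par > hi - 1e-4)
  }
  Q <- make_Q(rates)
  structure(
    list(Q = Q, loglik = mk_loglik(tree, tip_states, Q, root_prior),
         rates = rates, model = model, states = states,
         root_prior = root_prior, boundary = boundary,
         tree = tree, tip_states = tip_states),
    class = "mk_fit"
  )
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("<mk_fit> %s model, %d states, log-likelihood %.4f%s\n",
              x$model, length(x$states), x$loglik,
              if (x$boundary) " (rate at boundary)" else ""))
  print(round(x$Q, 6))
  invisible(x)
}

#' @export
tidy.mk_fit <- function(x, ...) {
  if (x$model == "ER") {
    tibble::tibble(term = "rate", estimate = x$rates[1])
  } else {
    tibble::tibble(
      term = c(paste0(x$states[1], "->", x$states[2]),
               paste0(x$states[2], "->", x$states[1])),
      estimate = x$rates
    )
  }
}

#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(
    logLik = as.numeric(x$loglik),
    model = x$model,
    n_states = length(x$states),
    n_tips = ape::Ntip(x$tree),
    boundary = x$boundary
  )
}

#' Exact marginal ancestral-state posteriors at every node
#'
#' Combined postorder/preorder message passing: the postorder pass computes
#' each node's below-partial likelihood, the preorder pass the complementary
#' above-likelihood; their normalized product is the exact marginal posterior
#' of the node's state given all tip data. Serves as the analytic oracle for
#' the stochastic character-map sampler.
#'
#' @inheritParams mk_loglik
#' @return Tibble: `node` (ape node number), `clade` (clade key for internal
#'   nodes, tip label for tips), one column per state with the posterior
#'   probability. Rows cover all nodes; internal nodes carry their clade keys.
#' @export
marginal_node_posteriors <- function(tree, tip_states, Q, root_prior = "equal") {
  tree <- validate_tree(tree)
  Q <- validate_generator(Q)
  prior <- resolve_root_prior(root_prior, Q)
  pr <- mk_prune(tree, tip_states, Q, prior)
  if (pr$dead) abort("data impossible under Q: zero likelihood")
  post <- pr$tree
  k <- pr$k
  ntip <- ape::Ntip(post)
  nnode <- ntip + post$Nnode
  # normalized child->parent messages per edge
  msg <- matrix(0, nrow(post$edge), k)
  for (e in seq_len(nrow(post$edge))) {
    v <- as.vector(pr$Pmats[[e]] %*% pr$partials[post$edge[e, 2], ])
    msg[e, ] <- v / sum(v)
  }
  child_edges <- split(seq_len(nrow(post$edge)), post$edge[, 1])
  above <- matrix(0, nnode, k)
  above[pr$root, ] <- prior
  # preorder = reverse postorder edge order
  for (e in rev(seq_len(nrow(post$edge)))) {
    par <- post$edge[e, 1]
    chi <- post$edge[e, 2]
    B <- above[par, ]
    for (e2 in child_edges[[as.character(par)]]) {
      if (e2 != e) B <- B * msg[e2, ]
    }
    v <- as.vector(B %*% pr$Pmats[[e]])
    above[chi, ] <- v / sum(v)
  }
  postp <- above * pr$partials
  postp <- postp / rowSums(postp)
  keys <- clade_keys(post)
  clade <- c(post$tip.label, unname(keys[as.character(ntip + seq_len(post$Nnode))]))
  out <- tibble::tibble(node = seq_len(nnode), clade = clade)
  for (j in seq_len(k)) out[[pr$states[j]]] <- postp[, j]
  out
}
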