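#' @keywords internal
#' Endpoint-conditioned CTMC path on one branch, by rejection sampling.
#' Returns a list(times, states) of jump times (from branch start) and the
#' new state index after each jump, or NULL if `max_attempts` is exhausted.
sample_path_rejection <- function(Q, t, a, b, max_attempts = 10000L) {
  k <- nrow(Q)
  for (att in seq_len(max_attempts)) {
    times <- numeric(0)
    sts <- integer(0)
    s <- a
    now <- 0
    if (a != b) {
      # at least one change must occur: draw the first waiting time from the
      # exponential truncated to (0, t)
      ra <- -Q[a, a]
      if (ra <= 0) return(NULL)
      u <- runif(1)
      now <- -log(1 - u * (1 - exp(-ra * t))) / ra
      p <- Q[s, ]
      p[s] <- 0
      s <- sample.int(k, 1, prob = p)
      times <- now
      sts <- s
    }
    repeat {
      r <- -Q[s, s]
      if (r <= 0) break
      now <- now + rexp(1, r)
      if (now >= t) break
      p <- Q[s, ]
      p[s] <- 0
      s <- sample.int(k, 1, prob = p)
      times <- c(times, now)
      sts <- c(sts, s)
    }
    if (s == b) return(list(times = times, states = sts))
  }
  NULL
}

#' @keywords internal
#' Endpoint-conditioned CTMC path by uniformization (fallback when rejection
#' is hopeless, e.g. an unlikely endpoint pair on a short branch).
sample_path_uniformization <- function(Q, t, a, b, Pt_ab) {
  k <- nrow(Q)
  mu <- max(-diag(Q))
  if (mu <= 0) {
    if (a == b) return(list(times = numeric(0), states = integer(0)))
    abort("cannot connect differing endpoint states under a zero-rate generator")
  }
  R <- diag(k) + Q / mu
  # number of uniformized jumps: p(n) ~ Pois(mu t) * R^n[a,b] / Pt[a,b]
  Rpow <- list(diag(k))
  nmax <- 1L
  repeat {
    Rpow[[nmax + 1L]] <- Rpow[[nmax]] %*% R
    pn <- vapply(0:nmax, function(n) {
      stats::dpois(n, mu * t) * Rpow[[n + 1L]][a, b]
    }, numeric(1))
    if (sum(pn) / Pt_ab > 1 - 1e-10 || nmax > 10000L) break
    nmax <- nmax + 1L
  }
  n <- sample.int(length(pn), 1, prob = pn) - 1L
  if (n == 0L) return(list(times = numeric(0), states = integer(0)))
  jump_times <- sort(runif(n, 0, t))
  sts <- integer(n)
  s <- a
  for (m in seq_len(n)) {
    # forward-filter/backward-sample over the uniformized chain
    w <- R[s, ] * Rpow[[n - m + 1L]][, b]
    sts[m] <- sample.int(k, 1, prob = w)
    s <- sts[m]
  }
  keep <- c(sts[1] != a, diff(sts) != 0)
  list(times = jump_times[keep], states = sts[keep])
}

#' Sample stochastic character maps
#'
#' Draws full character histories from their posterior given the tip states,
#' tree, and generator `Q`: the root state is sampled from its exact marginal
#' posterior, node states are sampled preorder proportional to the transition
#' probability times the child's below-partial likelihood, and each branch is
#' filled in with a continuous-time Markov path conditioned on its endpoint
#' states (rejection sampling with a capped attempt budget, uniformization as
#' the fallback). Endpoint consistency across branches is guaranteed by
#' construction.
#'
#' @inheritParams mk_loglik
#' @param n_maps Number of maps to draw.
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling cap per branch before switching to
#'   uniformization (default 10000).
#' @return List of `character_history` objects (see
#'   [simulate_mk_character()] for the layout).
#' @export
sample_character_histories <- function(tree, tip_states, Q, root_prior = "equal",
                                       n_maps = 100, seed = 1,
                                       max_attempts = 10000L) {
  tree <- validate_tree(tree)
  Q <- validate_generator(Q)
  prior <- resolve_root_prior(root_prior, Q)
  pr <- mk_prune(tree, tip_states, Q, prior)
  if (pr$dead) abort("data impossible under Q: zero likelihood")
  post <- pr$tree
  k <- pr$k
  states <- pr$states
  ntip <- ape::Ntip(post)
  nnode <- ntip + post$Nnode
  nedge <- nrow(post$edge)
  root_w <- prior * pr$partials[pr$root, ]
  root_w <- root_w / sum(root_w)
  pre <- rev(seq_len(nedge))
  with_seed(seed, {
    lapply(seq_len(n_maps), function(m) {
      node_state <- integer(nnode)
      node_state[pr$root] <- sample.int(k, 1, prob = root_w)
      ev <- list()
      for (e in pre) {
        par <- post$edge[e, 1]
        chi <- post$edge[e, 2]
        w <- pr$Pmats[[e]][node_state[par], ] * pr$partials[chi, ]
        node_state[chi] <- sample.int(k, 1, prob = w)
        a <- node_state[par]
        b <- node_state[chi]
        len <- post$edge.length[e]
        path <- sample_path_rejection(Q, len, a, b, max_attempts)
        if (is.null(path)) {
          path <- sample_path_uniformization(Q, len, a, b, pr$Pmats[[e]][a, b])
        }
        if (length(path$times) > 0L) {
          ev[[length(ev) + 1L]] <- tibble::tibble(
            edge = e, parent = par, child = chi,
            time = path$times, to_state = states[path$states]
          )
        }
      }
      events <- if (length(ev) > 0L) dplyr::bind_rows(ev) else {
        tibble::tibble(edge = integer(), parent = integer(), child = integer(),
                       time = numeric(), to_state = character())
      }
      structure(
        list(tree = post,
             states = setNames(states[node_state[seq_len(ntip)]], post$tip.label),
             node_states = states[node_state],
             events = events),
        class = "character_history"
      )
    })
  })
}

#' Pool stochastic-map node states over a posterior sample of trees
#'
#' For each tree in the sample the generator is re-estimated by maximum
#' likelihood (the empirical approach) and `n_maps_per_tree` character
#' histories are sampled; internal-node states are then pooled across all
#' (tree, map) draws by clade key, so that nodes are matched across trees by
#' the tip set they subtend rather than by node index. The pooled frequency of
#' each state is its posterior probability; the fraction of trees containing
#' each clade is reported alongside.
#'
#' @param trees A `multiPhylo` tree sample (or a single `phylo`).
#' @param tip_states Named character vector taxon -> state.
#' @param model Mk sub-model passed to [fit_mk()] (default `"ER"`).
#' @param root_prior Root-state prior (default `"equal"`).
#' @param n_maps_per_tree Maps per tree; default makes the total number of
#'   maps 1000 (e.g. 1 per tree for a 1000-tree sample).
#' @param seed Integer seed.
#' @return Object of class `node_pp`: tibble with `clade`, one `pp_<state>`
#'   column per state, `n_draws` (contributing (tree, map) draws), and
#'   `tree_coverage` (fraction of trees containing the clade), sorted by
#'   decreasing coverage and clade size. Attribute `n_total_draws` records
#'   `n_trees * n_maps_per_tree`.
#' @export
summarize_node_pp <- function(trees, tip_states, model = "ER",
                              root_prior = "equal", n_maps_per_tree = NULL,
                              seed = 1) {
  if (inherits(trees, "phylo")) trees <- c(structure(list(trees), class = "multiPhylo"))
  n_trees <- length(trees)
  if (n_trees == 0L) abort("empty tree sample")
  if (is.null(n_maps_per_tree)) n_maps_per_tree <- max(1L, round(1000 / n_trees))
  obs_states <- sort(unique(tip_states[!is.na(tip_states) & tip_states != "unknown"]))
  counts <- list()   # clade -> named state-count vector
  clade_trees <- list()  # clade -> number of trees containing it
  for (ti in seq_len(n_trees)) {
    tr <- trees[[ti]]
    fit <- fit_mk(tr, tip_states, model = model, root_prior = root_prior,
                  states = obs_states)
    maps <- sample_character_histories(
      tr, tip_states, fit$Q, root_prior = root_prior,
      n_maps = n_maps_per_tree, seed = spawn_seed(seed, paste0("tree", ti))
    )
    keys <- clade_keys(maps[[1]]$tree)
    ntip <- ape::Ntip(tr)
    node_ids <- ntip + seq_len(tr$Nnode)
    for (key in keys) {
      clade_trees[[key]] <- (clade_trees[[key]] %||% 0L) + 1L
    }
    for (mp in maps) {
      st <- mp$node_states[node_ids]
      for (j in seq_along(node_ids)) {
        key <- keys[[as.character(node_ids[j])]]
        cc <- counts[[key]] %||% setNames(numeric(length(obs_states)), obs_states)
        cc[st[j]] <- cc[st[j]] + 1
        counts[[key]] <- cc
      }
    }
  }
  clades <- names(counts)
  pp <- do.call(rbind, lapply(counts, function(cc) cc / sum(cc)))
  out <- tibble::tibble(
    clade = clades,
    n_draws = unname(vapply(counts, sum, numeric(1))),
    tree_coverage = unname(vapply(clades,
                                  function(cl) clade_trees[[cl]] / n_trees,
                                  numeric(1)))
  )
  for (s in obs_states) out[[paste0("pp_", s)]] <- unname(pp[, s])
  out <- dplyr::arrange(out, dplyr::desc(.data$tree_coverage),
                        dplyr::desc(nchar(.data$clade)))
  attr(out, "n_total_draws") <- n_trees * n_maps_per_tree
  attr(out, "model") <- model
  class(out) <- c("node_pp", class(out))
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Look up the pooled posterior probability of a state at one clade
#'
#' @param node_pp A `node_pp` table from [summarize_node_pp()].
#' @param taxa Tip labels subtended by the node of interest.
#' @param state State whose posterior probability to return.
#' @return Scalar posterior probability (`NA` if the clade never occurs).
#' @export
clade_pp <- function(node_pp, taxa, state) {
  key <- clade_key_of(taxa)
  row <- which(node_pp$clade == key)
  if (length(row) == 0L) return(NA_real_)
  node_pp[[paste0("pp_", state)]][row[1]]
}

#' @export
autoplot.node_pp <- function(object, state = NULL, ...) {
  pp_cols <- grep("^pp_", names(object), value = TRUE)
  if (is.null(state)) state <- sub("^pp_", "", pp_cols[length(pp_cols)])
  df <- tibble::tibble(
    clade = factor(object$clade, levels = rev(object$clade)),
    pp = object[[paste0("pp_", state)]],
    coverage = object$tree_coverage
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pp, y = .data$clade,
                                   alpha = .data$coverage)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = paste0("posterior probability (", state, ")"),
                  y = NULL, alpha = "tree coverage") +
    ggplot2::theme_minimal()
}
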