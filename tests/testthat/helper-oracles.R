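# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: brute-force path enumeration for the Brownian
# correlation, exhaustive state-assignment sums for the Mk likelihood and
# marginals, and direct-formula WAIC.

# root-to-tip path (edge indices) for a tip, by walking up the edge table
path_to_root <- function(tree, tip) {
  root <- ape::Ntip(tree) + 1L
  path <- integer(0)
  node <- tip
  while (node != root) {
    e <- which(tree$edge[, 2] == node)
    path <- c(path, e)
    node <- tree$edge[e, 1]
  }
  path
}

# correlation by explicit path intersection: shared branch length / height
bruteforce_correlation <- function(tree) {
  ntip <- ape::Ntip(tree)
  h <- max(ape::node.depth.edgelength(tree)[seq_len(ntip)])
  R <- diag(ntip)
  paths <- lapply(seq_len(ntip), path_to_root, tree = tree)
  for (i in seq_len(ntip - 1)) {
    for (j in seq.int(i + 1, ntip)) {
      shared <- intersect(paths[[i]], paths[[j]])
      R[i, j] <- R[j, i] <- sum(tree$edge.length[shared]) / h
    }
  }
  dimnames(R) <- list(tree$tip.label, tree$tip.label)
  R
}

# Mk likelihood by exhaustive enumeration over all internal-node state
# assignments; transition probabilities from numerically integrated expm
# (Matrix::expm), independent of the package's closed form.
bruteforce_mk_lik <- function(tree, tip_states, Q, root_prior) {
  k <- nrow(Q)
  states <- rownames(Q)
  ntip <- ape::Ntip(tree)
  nnode_int <- tree$Nnode
  root <- ntip + 1L
  Pm <- lapply(seq_len(nrow(tree$edge)), function(e) {
    as.matrix(Matrix::expm(Q * tree$edge.length[e]))
  })
  tip_idx <- match(tip_states[tree$tip.label], states)
  combos <- expand.grid(rep(list(seq_len(k)), nnode_int))
  total <- 0
  for (ci in seq_len(nrow(combos))) {
    assign_all <- c(tip_idx, as.integer(combos[ci, ]))
    p <- root_prior[assign_all[root]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * Pm[[e]][assign_all[tree$edge[e, 1]], assign_all[tree$edge[e, 2]]]
    }
    total <- total + p
  }
  total
}

# exact marginal posterior of each internal node by the same exhaustive sum
bruteforce_mk_marginals <- function(tree, tip_states, Q, root_prior) {
  k <- nrow(Q)
  ntip <- ape::Ntip(tree)
  nnode_int <- tree$Nnode
  root <- ntip + 1L
  states <- rownames(Q)
  Pm <- lapply(seq_len(nrow(tree$edge)), function(e) {
    as.matrix(Matrix::expm(Q * tree$edge.length[e]))
  })
  tip_idx <- match(tip_states[tree$tip.label], states)
  combos <- expand.grid(rep(list(seq_len(k)), nnode_int))
  post <- matrix(0, nnode_int, k)
  for (ci in seq_len(nrow(combos))) {
    assign_all <- c(tip_idx, as.integer(combos[ci, ]))
    p <- root_prior[assign_all[root]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * Pm[[e]][assign_all[tree$edge[e, 1]], assign_all[tree$edge[e, 2]]]
    }
    for (j in seq_len(nnode_int)) {
      post[j, combos[ci, j]] <- post[j, combos[ci, j]] + p
    }
  }
  post / rowSums(post)
}

# direct-formula WAIC from a loglik matrix (draws x observations)
bruteforce_waic <- function(ll) {
  lppd_i <- log(colMeans(exp(ll)))
  p_i <- apply(ll, 2, var)
  list(lppd = sum(lppd_i), p_waic = sum(p_i),
       waic = -2 * (sum(lppd_i) - sum(p_i)))
}

# random binary tip states guaranteed non-constant
random_binary_states <- function(taxa) {
  repeat {
    s <- sample(c("0", "1"), length(taxa), replace = TRUE)
    if (length(unique(s)) == 2L) return(setNames(s, taxa))
  }
}
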