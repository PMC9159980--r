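test_that("zero-rate maps carry no events; forced endpoint changes carry at least one", {
  tr <- simulate_yule_tree(5, seed = 51)
  tips0 <- setNames(rep("0", 5), tr$tip.label)
  maps <- sample_character_histories(tr, tips0, mk_er_matrix(1e-9, c("0", "1")),
                                     n_maps = 20, seed = 1)
  expect_true(all(vapply(maps, function(m) nrow(m$events) == 0, logical(1))))

  # two tips in different states: every map needs >= 1 event on the path
  tt <- parse_newick("(A:1,B:1);")
  maps2 <- sample_character_histories(tt, c(A = "0", B = "1"),
                                      mk_er_matrix(0.6, c("0", "1")),
                                      n_maps = 50, seed = 2)
  expect_true(all(vapply(maps2, function(m) nrow(m$events) >= 1, logical(1))))
})

test_that("sampled histories are endpoint-consistent along every branch", {
  tr <- simulate_yule_tree(6, seed = 53)
  h <- simulate_mk_character(tr, mk_er_matrix(1.5, c("0", "1")), seed = 54)
  skip_if(length(unique(h$states)) < 2)
  maps <- sample_character_histories(tr, h$states,
                                     mk_er_matrix(1.5, c("0", "1")),
                                     n_maps = 30, seed = 3)
  for (m in maps) {
    tre <- m$tree
    expect_identical(unname(m$node_states[seq_len(6)]), unname(m$states[tre$tip.label]))
    for (e in seq_len(nrow(tre$edge))) {
      ev <- m$events[m$events$edge == e, ]
      end <- if (nrow(ev) > 0) ev$to_state[nrow(ev)] else
        m$node_states[tre$edge[e, 1]]
      expect_identical(m$node_states[tre$edge[e, 2]], end)
      if (nrow(ev) > 0) {
        expect_true(all(diff(c(0, ev$time)) > 0))
        expect_lte(max(ev$time), tre$edge.length[e])
      }
    }
  }
})

test_that("node-state frequencies over many maps match the exact marginals", {
  tr <- simulate_yule_tree(5, seed = 57)
  tips <- random_binary_states(tr$tip.label)
  Q <- mk_er_matrix(0.9, c("0", "1"))
  n_maps <- 2000
  maps <- sample_character_histories(tr, tips, Q, n_maps = n_maps, seed = 4)
  freq <- Reduce(`+`, lapply(maps, function(m) m$node_states[6:9] == "1")) / n_maps
  exact <- marginal_node_posteriors(tr, tips, Q)$`1`[6:9]
  se <- sqrt(pmax(exact * (1 - exact), 1e-12) / n_maps)
  expect_true(all(abs(freq - exact) < pmax(3 * se, 1e-3)))
})

test_that("uniformization path sampler produces valid endpoint-conditioned paths", {
  Q <- mk_er_matrix(0.4, c("0", "1"))
  Pt <- mk_transition_matrix(Q, 2)
  set.seed(77)
  for (i in 1:200) {
    a <- sample(1:2, 1); b <- sample(1:2, 1)
    p <- burrowstats:::sample_path_uniformization(Q, 2, a, b, Pt[a, b])
    s <- a
    for (j in seq_along(p$states)) {
      expect_true(p$states[j] != s)  # virtual jumps removed
      s <- p$states[j]
    }
    expect_identical(s, b)
    if (length(p$times) > 1) expect_true(all(diff(p$times) > 0))
    expect_true(all(p$times >= 0 & p$times <= 2))
  }
  # event-count distribution sanity: conditioned on equal endpoints over a
  # short branch, most paths have zero events at a low rate
  n0 <- sum(vapply(1:300, function(i) {
    length(burrowstats:::sample_path_uniformization(
      mk_er_matrix(0.1, c("0", "1")), 0.5, 1, 1,
      mk_transition_matrix(mk_er_matrix(0.1, c("0", "1")), 0.5)[1, 1])$times) == 0
  }, logical(1)))
  expect_gt(n0, 280)
})

test_that("pooling over a repeated tree equals the single-tree run within MC error", {
  tr <- to_unit_height(ape::keep.tip(molerat_reference_tree(),
                                     c("Bs", "Bj", "Gc", "Ch", "Hg")))
  tips <- c(Bs = "present", Bj = "present", Gc = "present", Ch = "absent",
            Hg = "absent")
  rep10 <- structure(rep(list(tr), 10), class = "multiPhylo")
  pp10 <- summarize_node_pp(rep10, tips, n_maps_per_tree = 300, seed = 5)
  pp1 <- summarize_node_pp(tr, tips, n_maps_per_tree = 3000, seed = 6)
  m <- merge(as.data.frame(pp10)[, c("clade", "pp_present")],
             as.data.frame(pp1)[, c("clade", "pp_present")], by = "clade")
  expect_equal(m$pp_present.x, m$pp_present.y, tolerance = 0.05)
  expect_true(all(pp10$tree_coverage == 1))
  expect_equal(unique(pp10$n_draws), 3000)
})

test_that("clades present in a subset of trees get partial coverage and pooled PPs", {
  t1 <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
  t2 <- parse_newick("(((A:1,C:1):1,B:2):1,D:3);")
  trees <- structure(c(rep(list(t1), 5), rep(list(t2), 5)), class = "multiPhylo")
  tips <- c(A = "1", B = "1", C = "0", D = "0")
  pp <- summarize_node_pp(trees, tips, n_maps_per_tree = 20, seed = 7)
  ab <- pp[pp$clade == "A|B", ]
  expect_equal(ab$tree_coverage, 0.5)
  expect_equal(ab$n_draws, 100)       # 5 trees x 20 maps
  root <- pp[pp$clade == "A|B|C|D", ]
  expect_equal(root$tree_coverage, 1)
  expect_equal(root$n_draws, 200)
  # PP rows sum to 1
  expect_equal(pp$pp_0 + pp$pp_1, rep(1, nrow(pp)), tolerance = 1e-9)
})

test_that("clade_pp looks up by unordered taxon set", {
  t1 <- parse_newick("((A:1,B:1):1,C:2);")
  pp <- summarize_node_pp(t1, c(A = "1", B = "1", C = "0"),
                          n_maps_per_tree = 50, seed = 8)
  expect_equal(clade_pp(pp, c("B", "A"), "1"), clade_pp(pp, c("A", "B"), "1"))
  expect_true(is.na(clade_pp(pp, c("A", "C"), "1")))
})
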