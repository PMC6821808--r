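test_that("gaussian transform maps ranks to normal quantiles", {
  # equal weights share an average rank, hence one output value
  g <- k_n(4, w = 3)
  gt <- gaussian_transform(g)
  pos <- gt$weights[upper.tri(gt$weights)]
  expect_equal(pos, rep(0.5, 6)) # rank (m+1)/2 -> median of the target

  # three distinct weights land on the 1/4, 2/4, 3/4 normal quantiles
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 1; m[1, 3] <- m[3, 1] <- 10
  m[2, 3] <- m[3, 2] <- 100
  gt <- gaussian_transform(weighted_graph(m))
  got <- c(gt$weights[1, 2], gt$weights[1, 3], gt$weights[2, 3])
  expect_equal(got, 0.5 + 0.1 * qnorm(c(0.25, 0.5, 0.75)),
               tolerance = 1e-9)
  expect_equal(round(got, 4), c(0.4326, 0.5000, 0.5674))
})

test_that("gaussian transform preserves rank order, zeros and symmetry", {
  set.seed(71)
  g <- generate_connectome(synthetic_spec(40, 0.3, seed = 71))
  gt <- gaussian_transform(g)
  up <- upper.tri(g$weights)
  pos <- up & g$weights > 0
  expect_equal(cor(g$weights[pos], gt$weights[pos], method = "spearman"), 1)
  expect_true(all(gt$weights[up & g$weights == 0] == 0))
  expect_equal(gt$weights, t(gt$weights))

  # extreme parameters clip instead of producing nonpositive weights
  expect_warning(gc2 <- gaussian_transform(g, target_mean = 0,
                                           target_sd = 1), "clipped")
  expect_true(all(gc2$weights[pos] > 0))
  expect_error(gaussian_transform(weighted_graph(matrix(0, 3, 3))),
               "no positive weights")
})

test_that("transformed weights are consistent with a normal law", {
  g <- generate_connectome(synthetic_spec(60, 0.3, seed = 73))
  w <- g$weights
  m <- sum(upper.tri(w) & w > 0)
  expect_gte(m, 200)
  gt <- gaussian_transform(g)
  pos <- gt$weights[upper.tri(gt$weights) & gt$weights > 0]
  expect_gt(stats::shapiro.test(pos)$p.value, 0.01)
})

test_that("deletion cascades remove the right nodes and track components", {
  # star: hub (strength 3) goes first, component size 4 -> 1
  traj <- deletion_cascade(star_graph(3), "strength")
  expect_equal(traj$removed[1], "n1")
  expect_equal(traj$largest_component[1], 1)
  expect_equal(traj$n_remaining, c(3, 2, 1, 0))

  # K_3 ties broken by lowest index; component sizes 2, 1, 0
  traj <- deletion_cascade(k_n(3), "strength")
  expect_equal(traj$removed, c("n1", "n2", "n3"))
  expect_equal(traj$largest_component, c(2, 1, 0))

  empty <- deletion_cascade(weighted_graph(matrix(0, 0, 0)))
  expect_equal(nrow(empty), 0)
})

test_that("cascade invariants hold for every measure", {
  set.seed(79)
  g <- generate_connectome(synthetic_spec(25, 0.3, seed = 79))
  for (meas in c("strength", "betweenness", "curvature", "random")) {
    traj <- deletion_cascade(g, meas, seed = 5)
    expect_equal(nrow(traj), n_nodes(g))
    expect_setequal(traj$removed, g$node_ids)
    expect_true(all(diff(traj$largest_component) <= 0))
    expect_equal(traj$n_remaining, seq(n_nodes(g) - 1, 0))
  }
})

test_that("frozen-ranking cascades follow the initial strength sort", {
  set.seed(83)
  g <- generate_connectome(synthetic_spec(30, 0.3, seed = 83))
  traj <- deletion_cascade(g, "strength", recompute = FALSE)
  s0 <- node_strength(g)$value
  expected <- g$node_ids[order(-s0, seq_along(s0))]
  expect_equal(traj$removed, expected)
})

test_that("random cascades are reproducible from the seed", {
  g <- generate_connectome(synthetic_spec(20, 0.4, seed = 89))
  t1 <- deletion_cascade(g, "random", seed = 11)
  t2 <- deletion_cascade(g, "random", seed = 11)
  expect_identical(t1$removed, t2$removed)
  t3 <- deletion_cascade(g, "random", seed = 12)
  expect_false(identical(t1$removed, t3$removed))
})

test_that("strength-targeted deletion degrades the network at least as
           fast as random removal", {
  set.seed(97)
  n_seeds <- 5
  auc <- matrix(0, n_seeds, 4,
                dimnames = list(NULL, c("eff_s", "eff_r", "ent_s", "ent_r")))
  for (s in seq_len(n_seeds)) {
    g <- generate_connectome(synthetic_spec(40, 0.3, seed = 900 + s))
    ts <- deletion_cascade(g, "strength")
    tr <- deletion_cascade(g, "random", seed = s)
    auc[s, ] <- c(decay_auc(ts, "efficiency"), decay_auc(tr, "efficiency"),
                  decay_auc(ts, "entropy"), decay_auc(tr, "entropy"))
  }
  expect_lte(mean(auc[, "eff_s"]), mean(auc[, "eff_r"]))
  expect_lte(mean(auc[, "ent_s"]), mean(auc[, "ent_r"]))
})
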