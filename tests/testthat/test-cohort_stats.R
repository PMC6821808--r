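test_that("pernode t-tests match the pooled-variance closed form", {
  vals <- rbind(n1 = c(1, 2, 3, 4, 3, 4, 5, 6))
  groups <- rep(c("A", "B"), each = 4)
  tt <- pernode_ttest(vals, groups)
  expect_equal(tt$t_statistic, -2.190890, tolerance = 1e-6)
  expect_equal(tt$p_value, 2 * pt(-2.1908902, df = 6), tolerance = 1e-6)
  expect_equal(tt$p_value, 0.0709, tolerance = 2e-3)

  # identical groups: t = 0, p = 1 everywhere
  vals <- matrix(rep(c(1, 2, 3), 2), nrow = 2, ncol = 6, byrow = TRUE)
  tt <- pernode_ttest(vals, rep(c("A", "B"), each = 3))
  expect_equal(tt$t_statistic, c(0, 0))
  expect_equal(tt$p_value, c(1, 1))

  # zero pooled variance is flagged, not divided by
  vals <- rbind(c(0, 0, 0, 1, 1, 1))
  tt <- pernode_ttest(vals, rep(c("A", "B"), each = 3))
  expect_true(tt$zero_variance)
  expect_equal(tt$p_value, 1)
})

test_that("pernode t-tests agree with stats::t.test on random data", {
  set.seed(103)
  vals <- matrix(rnorm(20 * 12), 20, 12)
  groups <- rep(c("A", "B"), each = 6)
  tt <- pernode_ttest(vals, groups)
  tw <- pernode_ttest(vals, groups, var_equal = FALSE)
  for (i in c(1, 7, 20)) {
    ref <- t.test(vals[i, 1:6], vals[i, 7:12], var.equal = TRUE)
    expect_equal(tt$t_statistic[i], unname(ref$statistic), tolerance = 1e-9)
    expect_equal(tt$p_value[i], ref$p.value, tolerance = 1e-9)
    refw <- t.test(vals[i, 1:6], vals[i, 7:12])
    expect_equal(tw$p_value[i], refw$p.value, tolerance = 1e-9)
  }
})

test_that("holm_sidak applies the exact step-down thresholds", {
  # m = 1 reduces to the plain level-alpha test
  expect_true(holm_sidak(0.04, 0.05)$significant)
  expect_false(holm_sidak(0.06, 0.05)$significant)

  hs <- holm_sidak(c(0.01, 0.02, 0.04), 0.05)
  expect_equal(hs$significant, c(TRUE, TRUE, TRUE))

  hs <- holm_sidak(c(0.2, 0.3, 0.9), 0.05)
  expect_equal(hs$significant, c(FALSE, FALSE, FALSE))

  # the step-down stops at the first failure: a just-passing smallest p
  # cannot rescue a failing second one
  hs <- holm_sidak(c(0.01, 0.04, 0.9), 0.05)
  expect_equal(hs$significant, c(TRUE, FALSE, FALSE))

  # rejection set is a down-set of the sorted p-values
  set.seed(107)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))
    hs <- holm_sidak(p, 0.05)
    sig_sorted <- hs$significant[order(p)]
    if (any(sig_sorted))
      expect_true(all(sig_sorted[seq_len(max(which(sig_sorted)))]))
    # adjusted p-values reproduce the step-down decisions at the same level
    expect_equal(hs$p_adjusted <= 0.05, hs$significant)
  }
})

test_that("holm_sidak rejects a superset of Holm-Bonferroni", {
  set.seed(109)
  for (rep in 1:25) {
    m <- sample(5:50, 1)
    p <- runif(m)^2
    hs <- holm_sidak(p, 0.05)$significant
    hb <- p.adjust(p, "holm") <= 0.05
    expect_true(all(hb[hb] == hs[hb])) # every Holm rejection is kept
    expect_gte(sum(hs), sum(hb))
  }
})

test_that("group_compare recovers injected effects and stays quiet on
           null cohorts (curvature measure, small scale)", {
  spec <- synthetic_spec(n_nodes = 40, density = 0.35, seed = 113)
  targets <- c(3, 11, 27)
  eff <- effect_spec(targets, "weight_scale_down", 0.2)
  co <- generate_cohort(spec, n_per_group = 8, effect = eff)
  res <- group_compare(co, "curvature", alpha = 0.05)
  expect_equal(attr(res, "m"), 40)
  # the injected nodes lose incident weight; their strength must separate
  sres <- group_compare(co, "strength", alpha = 0.05)
  expect_true(all(sres$significant[targets]))
  expect_true(all(sres$mean_b[targets] < sres$mean_a[targets]))

  null_co <- generate_cohort(synthetic_spec(40, 0.35, seed = 127),
                             n_per_group = 8)
  nres <- group_compare(null_co, "strength", alpha = 0.05)
  expect_lte(sum(nres$significant), 2)
})

test_that("consistency maps count top-fraction membership per subject", {
  spec <- synthetic_spec(n_nodes = 16, density = 0.5, seed = 131)
  g <- generate_connectome(spec)
  co <- cohort(list(g, g, g))
  cm <- consistency_map(co, "strength", 0.25)
  expect_true(all(cm %in% c(0L, 3L)))
  expect_equal(sum(cm), 3 * ceiling(0.25 * 16))

  # single subject, N = 4, fraction 0.25 -> exactly one marked node
  one <- cohort(list(k_n(4)))
  vals <- matrix(c(4, 1, 2, 3), ncol = 1,
                 dimnames = list(paste0("n", 1:4), "s1"))
  cm <- consistency_map(one, values = vals, top_fraction = 0.25)
  expect_equal(sum(cm), 1)
  expect_equal(unname(cm["n1"]), 1L)

  # disjoint per-subject tops give count 1 everywhere marked
  vals3 <- cbind(s1 = c(9, 0, 0, 0), s2 = c(0, 9, 0, 0), s3 = c(0, 0, 9, 0))
  rownames(vals3) <- paste0("n", 1:4)
  co3 <- cohort(list(k_n(4), k_n(4), k_n(4)))
  cm <- consistency_map(co3, values = vals3, top_fraction = 0.25)
  expect_equal(max(cm), 1L)
  expect_equal(sum(cm), 3L)
  expect_error(consistency_map(co3, top_fraction = 1.2), "top_fraction")
})

test_that("cross-measure correlation histograms summarize per-subject r", {
  spec <- synthetic_spec(n_nodes = 30, density = 0.4, seed = 137)
  co <- generate_cohort(spec, n_per_group = 3)
  h <- measure_correlation_histogram(co, "strength", "strength")
  expect_true(all(h$r == 1))
  expect_equal(h$variance, 0)

  one <- cohort(list(generate_connectome(spec)))
  h1 <- measure_correlation_histogram(one, "strength", "clustering")
  expect_equal(h1$mean, unname(h1$r[1]))
  expect_equal(h1$variance, 0)

  # independent random measures: null mean near 0 across 30 subjects
  set.seed(139)
  nsub <- 30
  gs <- replicate(nsub, k_n(30), simplify = FALSE)
  conull <- cohort(gs)
  va <- matrix(rnorm(30 * nsub), 30, nsub)
  vb <- matrix(rnorm(30 * nsub), 30, nsub)
  rownames(va) <- rownames(vb) <- paste0("n", 1:30)
  hn <- measure_correlation_histogram(conull, values_a = va, values_b = vb)
  expect_lt(abs(hn$mean), 0.1)

  # a constant measure in one subject is skipped with a flag
  va[, 5] <- 1
  hs <- measure_correlation_histogram(conull, values_a = va, values_b = vb)
  expect_true(hs$skipped[5])
  expect_false(any(hs$skipped[-5]))
})
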