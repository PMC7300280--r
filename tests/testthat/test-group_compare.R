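# Kruskal-Wallis, Nemenyi post hoc, letters and period differences.

test_that("Kruskal-Wallis matches the explicit rank formula", {
  res <- kruskal_wallis(c(1:3, 4:6, 7:9), rep(c("a", "b", "c"), each = 3))
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(7.2, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(kruskal_wallis(rep(5, 9),
                              rep(c("a", "b", "c"), each = 3))$statistic, 0)
  set.seed(17)
  for (i in 1:40) {
    x <- if (i %% 2) rnorm(30) else sample(1:8, 30, replace = TRUE)  # ties
    g <- sample(c("a", "b", "c"), 30, replace = TRUE)
    if (min(table(factor(g, levels = c("a", "b", "c")))) == 0) next
    expect_equal(kruskal_wallis(x, g)$statistic, oracle_kw_H(x, g),
                 tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(19)
  x <- rgamma(36, 3); g <- rep(c("a", "b", "c"), 12)
  h0 <- kruskal_wallis(x, g)$statistic
  expect_equal(kruskal_wallis(exp(x), g)$statistic, h0, tolerance = 1e-12)
  expect_equal(kruskal_wallis(rank(x), g)$statistic, h0, tolerance = 1e-12)
})

test_that("chi-squared p tracks the exact permutation p where tests decide", {
  # exhaustive check on the balanced three-group design at n = 9: every
  # attainable statistic whose exact permutation p is in the decision
  # region has a chi-squared p within 0.03 of it; in the middle of the
  # highly discrete small-n distribution the gap is larger, a property of
  # the reference distributions themselves
  x <- 1:9
  g0 <- rep(c("a", "b", "c"), each = 3)
  perms <- gtools_permute_groups(9, c(3, 3, 3))
  Hs <- vapply(perms, function(idx) oracle_kw_H(x, g0[order(idx)]),
               numeric(1))
  for (a in unique(round(Hs, 10))) {
    p_exact <- mean(Hs >= a - 1e-9)
    if (p_exact > 0.12) next
    p_chi <- kruskal_wallis(x, g0[order(perms[[which.max(
      abs(Hs - a) < 1e-9)]])])$p_value
    expect_lt(abs(p_chi - p_exact), 0.03)
  }
})

test_that("Nemenyi separates shifted groups into letter classes", {
  # two identical groups: p ~ 1
  nn <- nemenyi_pairwise(rep(1:10, 2), rep(c("a", "b"), each = 10))
  expect_gt(nn$p_matrix["a", "b"], 0.95)
  expect_true(all(nn$p_matrix == t(nn$p_matrix)))
  # two equal groups and one strongly shifted: letters {a, a, b}
  set.seed(29)
  x <- c(rnorm(20, 0), rnorm(20, 0), rnorm(20, 50))
  g <- rep(c("g1", "g2", "g3"), each = 20)
  nn <- nemenyi_pairwise(x, g)
  expect_equal(unname(nn$letters[c("g1", "g2")]), c("a", "a"))
  expect_equal(unname(nn$letters["g3"]), "b")
  expect_lt(nn$p_matrix["g1", "g3"], 0.05)
  expect_gt(nn$p_matrix["g1", "g2"], 0.05)
  expect_error(nemenyi_pairwise(x, factor(g, levels = c(unique(g), "g4"))),
               "empty group")
})

test_that("post hoc decisions rarely contradict a quiet omnibus", {
  set.seed(31)
  viol <- 0
  for (i in 1:300) {
    x <- rnorm(36)
    g <- rep(c("a", "b", "c"), each = 12)
    kw <- kruskal_wallis(x, g)
    nn <- nemenyi_pairwise(x, g)
    if (kw$p_value >= 0.05 &&
        any(nn$p_matrix[upper.tri(nn$p_matrix)] < 0.05)) viol <- viol + 1
  }
  expect_lt(viol / 300, 0.01)
})

test_that("period anomalies are antisymmetric and tested per tree", {
  set.seed(37)
  mk <- function(shift2) do.call(rbind, lapply(1:20, function(i) {
    base <- rnorm(1, 2000, 300)
    rbind(long_series(paste0("t", i), 1880:1915, base + rnorm(36, 0, 300)),
          long_series(paste0("t", i), 1980:2015,
                      base + shift2 + rnorm(36, 0, 300)))
  }))
  x <- mk(0)
  pd <- period_difference(x, c(1880, 1915), c(1980, 2015))
  pd_swap <- period_difference(x, c(1980, 2015), c(1880, 1915))
  expect_equal(pd$trees$anomaly, -pd_swap$trees$anomaly)
  # identical windows: all anomalies zero
  same <- period_difference(x, c(1880, 1915), c(1880, 1915))
  expect_true(all(same$trees$anomaly == 0))
  # trees missing a window are excluded with a message
  x_miss <- rbind(x, long_series("lonely", 1880:1915, rnorm(36, 2000)))
  expect_message(pd2 <- period_difference(x_miss, c(1880, 1915),
                                          c(1980, 2015)), "lonely")
  expect_false("lonely" %in% pd2$trees$tree_id)
})

test_that("a planted +1000 growth shift is detected at 0.01", {
  set.seed(41)
  hits <- 0
  for (rep in 1:30) {
    x <- do.call(rbind, lapply(1:20, function(i) {
      base <- rnorm(1, 2000, 300)
      rbind(long_series(paste0("t", i), 1880:1915, base + rnorm(36, 0, 300)),
            long_series(paste0("t", i), 1980:2015,
                        base + 1000 + rnorm(36, 0, 300)))
    }))
    pd <- period_difference(x, c(1880, 1915), c(1980, 2015))
    if (pd$within$sig99) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.95)
})
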