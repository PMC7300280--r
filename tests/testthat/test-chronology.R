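# BAI geometry, interseries statistics, EPS, chronology assembly,
# trends, filtering and chronology correlation.

test_that("BAI conversion matches disc geometry on hand cases", {
  s <- ring_series("T", 1900, 1.0)
  expect_equal(bai_from_widths(s)$bai, pi)
  s <- ring_series("T", 1900, c(1.0, 1.0))
  expect_equal(bai_from_widths(s)$bai, c(pi, 3 * pi))
  s <- ring_series("T", 1900, c(2.0, 0.0))
  expect_equal(bai_from_widths(s)$bai, c(4 * pi, 0))
  # constant width => strictly increasing BAI (geometry)
  s <- ring_series("T", 1900, rep(0.8, 50))
  expect_true(all(diff(bai_from_widths(s)$bai) > 0))
})

test_that("BAI equals the brute-force oracle and conserves total area", {
  set.seed(11)
  for (i in 1:50) {
    w <- rgamma(sample(5:60, 1), shape = 6, rate = 3)
    r0 <- sample(c(0, 2.5, 10), 1)
    s <- ring_series("T", 1850, w)
    got <- bai_from_widths(s, initial_radius = r0)$bai
    expect_equal(got, oracle_bai(w, r0), tolerance = 1e-12)
    r_final <- r0 + sum(w)
    expect_equal(sum(got), pi * (r_final^2 - r0^2), tolerance = 1e-9)
  }
})

test_that("mean interseries correlation agrees with the pairwise loop", {
  expect_equal(mean_interseries_r(rbind(
    long_series("a", 1:10, sin(1:10)),
    long_series("b", 1:10, sin(1:10)))), 1)
  expect_equal(mean_interseries_r(rbind(
    long_series("a", 1:10, sin(1:10)),
    long_series("b", 1:10, -sin(1:10)))), -1)
  set.seed(3)
  common <- rnorm(40)
  memb <- do.call(rbind, lapply(1:5, function(i)
    long_series(paste0("t", i), 1901:1940,
                sqrt(0.4) * common + sqrt(0.6) * rnorm(40))))
  mat <- sapply(split(memb$value, memb$tree_id), identity)
  expect_equal(mean_interseries_r(memb), oracle_mean_r(mat),
               tolerance = 1e-12)
  expect_error(mean_interseries_r(rbind(
    long_series("a", 1:5, rnorm(5)), long_series("b", 11:15, rnorm(5)))),
    "overlap")
})

test_that("EPS reproduces the closed form and is monotone", {
  expect_equal(eps(1, 20), 1)
  expect_equal(eps(0.3, 20), 6 / 6.7, tolerance = 1e-12)   # ~0.8955
  expect_equal(eps(0.3, 2), 0.6 / 1.3, tolerance = 1e-12)  # ~0.4615
  expect_true(eps(0.3, 20) > 0.85)  # reliable
  expect_false(eps(0.3, 2) > 0.85)
  grid_r <- seq(0.05, 0.95, by = 0.05)
  grid_n <- 2:40
  for (r in grid_r) expect_true(all(diff(eps(r, grid_n)) > 0))
  for (n in grid_n) expect_true(all(diff(eps(grid_r, n)) > 0))
  expect_warning(e <- eps(-0.6, 3), "undefined")  # n*rbar + (1-rbar) <= 0
  expect_true(is.na(e))
})

test_that("chronologies average exactly the members present each year", {
  one <- long_series("solo", 1900:1909, 1:10)
  ch <- build_chronology(one, "BAI")
  expect_equal(ch$series$mean, as.numeric(1:10))
  expect_equal(ch$series$depth, rep(1L, 10))

  two <- rbind(long_series("a", 1901:1902, c(2, 4)),
               long_series("b", 1901:1902, c(4, 6)))
  expect_equal(build_chronology(two, "BAI")$series$mean, c(3, 5))

  # staggered starts: depth steps at entry, means recomputed per year
  memb <- rbind(long_series("a", 1900:1909, rep(2, 10)),
                long_series("b", 1905:1909, rep(4, 5)),
                long_series("c", 1907:1909, rep(9, 3)))
  ch <- build_chronology(memb, "BAI")
  oracle_mean <- sapply(1900:1909, function(y)
    mean(memb$value[memb$year == y]))
  expect_equal(ch$series$mean, oracle_mean)
  expect_equal(ch$series$depth, c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L))
  expect_error(build_chronology(memb[0, ], "BAI"), "no member data")

  # permutation invariance
  perm <- memb[sample(nrow(memb)), ]
  expect_equal(build_chronology(perm, "BAI")$series, ch$series)
})

test_that("linear trends recover planted slopes and reject honestly", {
  d <- data.frame(year = 1980:2015, value = 2 * (1980:2015) + 5)
  tr <- linear_trend(d)
  expect_equal(tr$slope, 2, tolerance = 1e-12)
  expect_true(tr$p < 1e-10)
  flat <- data.frame(year = 1980:2015, value = rep(3.3, 36))
  expect_equal(linear_trend(flat)$slope, 0, tolerance = 1e-12)
  expect_error(linear_trend(d[1:2, ]), ">= 3 points")
  set.seed(21)
  rej <- mean(replicate(400, {
    linear_trend(data.frame(year = 1:36, value = rnorm(36)))$significant
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("high-pass filtering removes slow structure only", {
  expect_true(all(highpass(rep(5, 30), 10) == 0, na.rm = TRUE))
  lin <- highpass(0.3 * (1:40), 10)
  expect_lt(max(abs(lin), na.rm = TRUE), 1e-10)
  # a 4-yr wave passes nearly untouched
  wave <- sin(2 * pi * (1:60) / 4)
  hp <- highpass(wave, 10)
  ok <- !is.na(hp)
  expect_gt(cor(hp[ok], wave[ok]), 0.99)
  expect_error(highpass(1:5, 10), "window exceeds")
})

test_that("the 10-yr spline splits a series into smooth + residual", {
  x <- rep(2.5, 40)
  expect_equal(spline_smooth(x, 10), x, tolerance = 1e-9)
  # smooth passes slow structure: a 40-yr wave survives nearly intact
  slow <- sin(2 * pi * (1:80) / 40)
  sm <- spline_smooth(slow, 10)
  expect_gt(cor(sm, slow), 0.99)
  expect_gt(sd(sm) / sd(slow), 0.8)
  # and attenuates a 4-yr wave strongly
  fast <- sin(2 * pi * (1:80) / 4)
  expect_lt(sd(spline_smooth(fast, 10)) / sd(fast), 0.2)
})

test_that("chronology correlation flags significance from the t reference", {
  a <- data.frame(year = 1901:1960, value = sin(1:60) + 0.05 * (1:60))
  self <- chronology_correlation(a, a)
  expect_equal(self$r, 1)
  expect_true(self$sig99)
  set.seed(5)
  b <- data.frame(year = 1901:1960, value = rnorm(60))
  expect_error(chronology_correlation(a[1:5, ], b[1:5, ]), "10 common years")
  # planted shared forcing: r estimates the shared variance fraction
  share <- 0.5
  reps <- replicate(200, {
    f <- rnorm(36)
    x <- sqrt(share) * f + sqrt(1 - share) * rnorm(36)
    y <- sqrt(share) * f + sqrt(1 - share) * rnorm(36)
    chronology_correlation(data.frame(year = 1:36, value = x),
                           data.frame(year = 1:36, value = y))$r
  })
  expect_equal(mean(reps), share, tolerance = 0.06)
})
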