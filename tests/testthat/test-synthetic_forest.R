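# Determinism, inversion identities and emulation targets of the
# synthetic-forest generator.

test_that("identical scenarios generate bit-identical forests", {
  a <- generate_forest(forest_scenario(seed = 12, trees_per_group = 4,
                                       isotope_trees_per_group = 2))
  b <- generate_forest(forest_scenario(seed = 12, trees_per_group = 4,
                                       isotope_trees_per_group = 2))
  expect_identical(a$climate, b$climate)
  expect_identical(a$atmosphere, b$atmosphere)
  expect_identical(a$isotopes, b$isotopes)
  expect_identical(a$trees, b$trees)
  c <- generate_forest(forest_scenario(seed = 13, trees_per_group = 4,
                                       isotope_trees_per_group = 2))
  expect_false(identical(a$trees$bai$bai, c$trees$bai$bai))
})

test_that("zero noise and zero trend give a periodic climate", {
  sc <- forest_scenario(seed = 1, climate = list(
    warming_per_year = 0, precip_trend_per_year = 0, tmean_year_sd = 0,
    tmean_month_sd = 0, precip_year_sd = 0, precip_month_sd = 0))
  cl <- generate_climate(sc)$true
  jan <- cl$tmean[cl$month == 1]
  expect_equal(max(jan) - min(jan), 0)
  jul_p <- cl$psum[cl$month == 7]
  expect_equal(max(jul_p) - min(jul_p), 0)
  # summer is the dry season, winter the cold one
  expect_lt(cl$psum[cl$month == 7][1], cl$psum[cl$month == 1][1])
  expect_gt(cl$tmean[cl$month == 7][1], cl$tmean[cl$month == 1][1])
})

test_that("the configured warming contrast is realised between windows", {
  diffs <- sapply(1:15, function(s) {
    cl <- with_seed(s, generate_climate(forest_scenario(seed = s)))$true
    annual <- tapply(cl$tmean, cl$year, mean)
    yrs <- as.integer(names(annual))
    mean(annual[yrs %in% 1980:2015]) - mean(annual[yrs %in% 1880:1915])
  })
  expect_lt(abs(mean(diffs) - 1.3), 0.2)
  # and the long record is the exact configured transform of the truth
  sc <- forest_scenario(seed = 4)
  cl <- with_seed(4, generate_climate(sc))
  common <- cl$long$year %in% cl$true$year
  idx <- match(paste(cl$long$year, cl$long$month),
               paste(cl$true$year, cl$true$month))
  expect_equal(cl$long$tmean, cl$true$tmean[idx] + 5.8)
  expect_equal(cl$long$psum, cl$true$psum[idx] * 0.45)
  # rescaling the long record onto the target recovers the truth
  merged <- rescale_long_record(cl$long, cl$target)
  idx2 <- match(paste(cl$true$year, cl$true$month),
                paste(merged$year, merged$month))
  ok <- !is.na(idx2)
  expect_equal(merged$tmean[idx2[ok]], cl$true$tmean[ok], tolerance = 1e-9)
  expect_equal(merged$psum[idx2[ok]], cl$true$psum[ok], tolerance = 1e-9)
})

test_that("the CO2 path is monotone through its endpoints with the
           configured window ranges", {
  atm <- generate_atmosphere(forest_scenario())
  expect_equal(min(atm$ca), 288)
  expect_equal(max(atm$ca), 400.5)
  expect_true(all(diff(atm$ca) > 0))
  expect_true(atm$ca[atm$year == 1898] > 290 &&
                atm$ca[atm$year == 1898] < 302)
  expect_true(atm$ca[atm$year == 1998] > 338 &&
                atm$ca[atm$year == 1998] < 400)
  expect_true(all(diff(atm$d13c_atm) < 0))
  # Suess off: flat atmospheric d13C at the reference
  atm0 <- generate_atmosphere(forest_scenario(
    atmosphere = list(suess = FALSE)))
  expect_equal(unique(atm0$d13c_atm), -6.4)
})

test_that("generated isotopes invert exactly through the package chain", {
  fo <- generate_forest(forest_scenario(seed = 21, trees_per_group = 3,
                                        isotope_trees_per_group = 3))
  for (id in unique(fo$isotopes$d13c$tree_id)[1:3]) {
    d <- fo$isotopes$d13c[fo$isotopes$d13c$tree_id == id, ]
    tr <- fo$isotopes$truth[fo$isotopes$truth$tree_id == id, ]
    ch <- iwue_series(data.frame(year = d$year, d13c = d$d13c),
                      fo$atmosphere)
    expect_lt(max(abs(ch$iwue - tr$iwue)), 1e-9)
    expect_lt(max(abs(ch$delta - tr$delta)), 1e-9)
  }
  # zero sensitivity, zero noise, Suess off: constant measured d13C
  fo0 <- generate_forest(forest_scenario(
    seed = 2, trees_per_group = 2, isotope_trees_per_group = 1,
    atmosphere = list(suess = FALSE),
    isotope = list(summer_t_sens = 0, resid_sd = 0)))
  d <- fo0$isotopes$d13c[fo0$isotopes$d13c$tree_id == "QuPe_01", ]
  expect_equal(sd(d$d13c), 0)
})

test_that("generated widths invert to the generated BAI and metadata", {
  fo <- generate_forest(forest_scenario(seed = 31, trees_per_group = 3,
                                        isotope_trees_per_group = 2))
  for (id in names(fo$trees$rings)[c(1, 5, 9)]) {
    s <- fo$trees$rings[[id]]
    got <- bai_from_widths(s)$bai
    want <- fo$trees$bai$bai[fo$trees$bai$tree_id == id]
    expect_lt(max(abs(got - want) / want), 1e-9)
    dbh <- fo$trees$meta$dbh[fo$trees$meta$tree_id == id]
    expect_equal(dbh, 2 * sum(s$widths) / 10, tolerance = 1e-12)
  }
  # gamma moments: sample mean of BAI within 3 SE of the configured mean
  sc <- fo$scenario
  w1 <- fo$trees$bai[fo$trees$bai$year %in% 1880:1915, ]
  n <- nrow(w1)
  # the configured mean on the log scale plus the lognormal-ish corrections
  expect_lt(abs(mean(w1$bai) - exp(sc$growth$log_bai_mean)) /
              exp(sc$growth$log_bai_mean), 0.25)
  # noise-free growth: constant BAI means strictly decreasing widths
  fo0 <- generate_forest(forest_scenario(
    seed = 3, trees_per_group = 1, isotope_trees_per_group = 1,
    growth = list(beta = c(SuT = 0), sd_intercept = 0, sd_iwue_slope = 0,
                  shape = 1e9)))
  s <- fo0$trees$rings[[1]]
  expect_lt(sd(fo0$trees$bai$bai[fo0$trees$bai$tree_id == s$tree_id]) /
              mean(fo0$trees$bai$bai), 1e-3)
  expect_true(all(diff(s$widths) < 0))
})

test_that("generated files round-trip through the io module", {
  fo <- generate_forest(forest_scenario(seed = 41, trees_per_group = 3,
                                        isotope_trees_per_group = 2))
  dir <- withr::local_tempdir()
  write_forest(fo, dir)
  rings <- read_rwl(file.path(dir, "cores.rwl"))
  expect_equal(length(rings), 9L)
  meta <- read_tree_meta(file.path(dir, "trees.csv"))
  iso <- read_isotope_series(file.path(dir, "d13c.csv"), meta)
  atm <- read_atmosphere(file.path(dir, "atm.csv"))
  target <- read_monthly_climate(file.path(dir, "climate_target.csv"))
  long <- read_monthly_climate(file.path(dir, "climate_long.csv"))
  merged <- rescale_long_record(long, target)
  expect_true(validate_dataset(rings, meta, iso, atm, merged,
                               windows = list(c(1880, 1915),
                                              c(1980, 2015))))
  # widths survive the 0.001 mm quantisation
  s <- fo$trees$rings[[1]]
  expect_equal(rings[[s$tree_id]]$widths, round(s$widths, 3))
})
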