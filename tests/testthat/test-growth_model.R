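# Collinearity screening, the gamma model backends, model enumeration,
# random-effect LRTs and skill metrics.

make_gamma_data <- function(n = 300, beta = c(0.3, -0.2), shape = 10,
                            seed = 1, n_trees = 30) {
  with_seed(seed, {
    X <- matrix(rnorm(n * length(beta)), n)
    colnames(X) <- paste0("x", seq_along(beta))
    mu <- exp(1.5 + as.numeric(X %*% beta))
    d <- data.frame(bai = rgamma(n, shape, rate = shape / mu), X)
    d$tree_id <- factor(rep_len(paste0("t", seq_len(n_trees)), n))
    d$year <- rep_len(2001:2040, n)
    d
  })
}

test_that("VIF matches the auxiliary-regression oracle", {
  set.seed(43)
  n <- 200
  Z <- matrix(rnorm(n * 3), n)
  L <- chol(matrix(c(1, .6, .6, .6, 1, .6, .6, .6, 1), 3))
  X <- as.data.frame(Z %*% L)
  names(X) <- c("a", "b", "c")
  expect_equal(unname(vif(X)), unname(oracle_vif(X)), tolerance = 1e-8)
  # orthogonal-ish predictors: VIF ~ 1, nothing dropped at threshold 2
  O <- as.data.frame(qr.Q(qr(matrix(rnorm(n * 4), n))))
  names(O) <- paste0("o", 1:4)
  expect_true(all(vif(O) < 1.1))
  expect_equal(vif_filter(O)$retained, names(O))
})

test_that("VIF filtering drops duplicates deterministically", {
  set.seed(47)
  X <- data.frame(x1 = rnorm(100))
  X$x2 <- X$x1              # exact duplicate
  X$x3 <- rnorm(100)
  expect_warning(vf <- vif_filter(X), "perfectly collinear")
  expect_equal(vf$retained, c("x1", "x3"))
  expect_equal(vf$dropped$variable, "x2")
  # the same input always drops the same column
  expect_warning(vf2 <- vif_filter(X), "perfectly collinear")
  expect_identical(vf$retained, vf2$retained)
  # iterative removal stops when all VIF <= threshold
  Y <- data.frame(a = rnorm(200))
  Y$b <- Y$a + rnorm(200, sd = 0.3)   # heavily shared
  Y$c <- rnorm(200)
  vf3 <- vif_filter(Y, threshold = 2)
  expect_true(all(vif(data.frame(Y[vf3$retained], z = rnorm(200)))
                  [vf3$retained] <= 2))
})

test_that("the random-free fit equals direct gamma maximum likelihood", {
  for (seed in 1:8) {
    d <- make_gamma_data(seed = seed)
    fit <- fit_growth_model(d, c("x1", "x2"), "none")
    orc <- oracle_gamma_glm(cbind(1, d$x1, d$x2), d$bai)
    expect_equal(fit$coefficients$estimate, unname(orc$beta),
                 tolerance = 1e-4)
    expect_equal(fit$shape, orc$shape, tolerance = 1e-3)
    expect_equal(fit$loglik, orc$loglik, tolerance = 1e-6)
  }
  # intercept-only: coefficient is log of the sample mean
  d <- make_gamma_data(seed = 99)
  f0 <- fit_growth_model(d, character(), "none")
  expect_equal(f0$coefficients$estimate, log(mean(d$bai)),
               tolerance = 1e-8)
  expect_error(fit_growth_model(transform(d, bai = bai - 10), "x1", "none"),
               "> 0")
})

test_that("glmmTMB and glm backends agree when variances vanish", {
  d <- make_gamma_data(seed = 7)
  plain <- fit_growth_model(d, c("x1", "x2"), "none")
  mixed <- fit_growth_model(d, c("x1", "x2"), "intercept")
  # data carry no tree structure: the mixed fit collapses to the GLM
  expect_lt(sqrt(mixed$ranef_var[["intercept"]]), 0.1)
  expect_equal(mixed$coefficients$estimate, plain$coefficients$estimate,
               tolerance = 1e-2)
  expect_lt(abs(mixed$loglik - plain$loglik), 0.5)
})

test_that("t statistics are invariant to affine predictor rescaling", {
  d <- make_gamma_data(seed = 3)
  f1 <- fit_growth_model(d, c("x1", "x2"), "none")
  d2 <- transform(d, x1 = 100 * x1 - 7, x2 = 0.01 * x2 + 3)
  f2 <- fit_growth_model(d2, c("x1", "x2"), "none")
  expect_equal(f1$coefficients$t[-1], f2$coefficients$t[-1],
               tolerance = 1e-6)
})

test_that("AICc applies the small-sample correction", {
  expect_equal(aicc(-100, 5, 50), 200 + 10 + 2 * 5 * 6 / 44)
  expect_equal(aicc(-100, 5, 6), Inf)
  d <- make_gamma_data(seed = 5)
  f <- fit_growth_model(d, "x1", "none")
  expect_equal(f$aicc, aicc(f$loglik, f$k, f$n))
})

test_that("a two-model race picks the lower AICc and nesting holds", {
  d <- make_gamma_data(seed = 11, beta = c(0.5, 0))
  sel <- enumerate_and_select(d, c("x1"), "none", delta = 0)
  with_x <- fit_growth_model(d, "x1", "none")
  without <- fit_growth_model(d, character(), "none")
  expect_equal(sel$best$aicc, min(with_x$aicc, without$aicc))
  # likelihood of the larger fixed model is never below the nested one
  expect_gte(with_x$loglik, without$loglik - 1e-6)
})

test_that("pure-noise predictors raise AICc in expectation", {
  set.seed(53)
  deltas <- replicate(60, {
    d <- make_gamma_data(seed = sample.int(1e6, 1), beta = c(0.5, 0))
    f_true <- fit_growth_model(d, "x1", "none")
    f_noise <- fit_growth_model(d, c("x1", "x2"), "none")
    f_noise$aicc - f_true$aicc
  })
  expect_gt(mean(deltas), 0)
})

test_that("random-effect LRT handles identity and boundary nulls", {
  fo <- generate_forest(forest_scenario(seed = 5, trees_per_group = 10))
  md <- build_model_data(fo$trees$bai, fo$trees$meta, fo$seasonal,
                         fo$isotopes$truth_group, c(1880, 1915))
  full <- fit_growth_model(md, c("iwue", "WiT"), "intercept+iwue")
  ri <- fit_growth_model(md, c("iwue", "WiT"), "intercept")
  none <- fit_growth_model(md, c("iwue", "WiT"), "none")
  same <- lrt_random(ri, ri)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  lt <- lrt_random(ri, none)
  expect_equal(lt$df, 1)
  expect_true(lt$p_value < 0.05)  # planted intercept SD 0.2 is detectable
  expect_error(lrt_random(none, ri), "not nested")
  expect_error(lrt_random(full, fit_growth_model(md, "iwue", "intercept")),
               "fixed effects differ")
})

test_that("predictive skill is exact for a perfect model and honest
           otherwise", {
  fo <- generate_forest(forest_scenario(seed = 9, trees_per_group = 8))
  md <- build_model_data(fo$trees$bai, fo$trees$meta, fo$seasonal,
                         fo$isotopes$truth_group, c(1880, 1915))
  f <- fit_growth_model(md, c("iwue", "SuP", "WiT"), "intercept")
  sk <- predictive_skill(f, nsim = 50, seed = 1)
  expect_true(sk$marginal_r2 > 0 && sk$marginal_r2 < 1)
  expect_true(sk$chron_r > 0)
  expect_true(all(sk$band$upper >= sk$band$lower))
  # perfect predictions: adjusted R2 and chronology r are 1
  f2 <- f
  f2$fitted <- md$bai
  sk2 <- predictive_skill(f2, nsim = 10, seed = 1)
  expect_equal(sk2$adj_r2, 1, tolerance = 1e-12)
  expect_equal(sk2$chron_r, 1, tolerance = 1e-12)
  # intercept-only: constant prediction, correlation reported as NA
  f0 <- fit_growth_model(md, character(), "none")
  sk0 <- predictive_skill(f0, nsim = 10, seed = 1)
  expect_true(is.na(sk0$chron_r))
})

test_that("the generator's planted link-scale variance share is recovered", {
  # single strong driver, no random effects: true marginal R2 = 0.6
  beta_su <- sqrt(0.6 / 0.4 * trigamma(15))
  r2s <- sapply(1:6, function(s) {
    fo <- generate_forest(forest_scenario(
      seed = s, trees_per_group = 10,
      growth = list(beta = c(SuT = beta_su), sd_intercept = 0,
                    sd_iwue_slope = 0)))
    md <- build_model_data(fo$trees$bai, fo$trees$meta, fo$seasonal,
                           fo$isotopes$truth_group, c(1880, 1915))
    f <- fit_growth_model(md, "SuT", "none")
    predictive_skill(f, nsim = 10, seed = s)$marginal_r2
  })
  expect_lt(abs(mean(r2s) - 0.6), 0.1)
})
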