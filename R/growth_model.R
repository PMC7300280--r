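# Gamma mixed model of growth: collinearity screening, model fitting
# (glmmTMB backend; exact-ML gamma GLM path for random-free structures),
# AICc-based selection over a crossed model set, boundary-corrected LRTs
# for random effects, and predictive-skill diagnostics.

#' Variance inflation factors
#'
#' VIF_j = 1/(1 - R^2_j) where R^2_j is from regressing predictor j on all
#' others; computed from the inverse of the predictor correlation matrix,
#' with a regression fallback when that matrix is numerically singular
#' (perfectly collinear predictors get `Inf`).
#'
#' @param x Data frame or matrix of numeric candidate predictors.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  x <- x[num]
  if (ncol(x) < 2) abort("vif needs >= 2 predictors")
  if (nrow(x) <= ncol(x)) abort("vif needs more observations than predictors")
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0)) abort("vif: constant predictor(s): ",
                           paste(names(x)[sds == 0], collapse = ", "))
  R <- stats::cor(as.matrix(x))
  out <- tryCatch(diag(solve(R)), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out)) || any(out < 1 - 1e-8)) {
    # singular correlation matrix: per-column auxiliary regressions
    out <- vapply(seq_len(ncol(x)), function(j) {
      fit <- stats::lm.fit(cbind(1, as.matrix(x[-j])), x[[j]])
      rss <- sum(fit$residuals^2)
      tss <- sum((x[[j]] - mean(x[[j]]))^2)
      if (rss / tss < 1e-12) Inf else tss / rss
    }, numeric(1))
  }
  stats::setNames(pmax(out, 1), colnames(x))
}

#' Iterative VIF screening
#'
#' Drops the highest-VIF predictor until all VIFs are at or below the
#' threshold. Exactly duplicated (perfectly collinear) predictors are
#' removed first, keeping the earliest column, with a warning. Ties at the
#' maximum are broken by column order (the earlier column is kept).
#'
#' @param x Data frame of candidate predictors.
#' @param threshold Maximum admissible VIF (default 2, the screen used for
#'   the growth model).
#' @return List with `retained` (names), `dropped` (data frame `variable`,
#'   `vif`, `step`), `vif` (final VIF table).
#' @export
vif_filter <- function(x, threshold = 2) {
  x <- as.data.frame(x)
  dropped <- data.frame(variable = character(), vif = numeric(),
                        step = integer(), stringsAsFactors = FALSE)
  step <- 0L
  # remove exact duplicates deterministically (keep first occurrence)
  repeat {
    if (ncol(x) < 2) break
    R <- abs(stats::cor(as.matrix(x)))
    diag(R) <- 0
    hit <- which(R > 1 - 1e-10, arr.ind = TRUE)
    if (!nrow(hit)) break
    j <- max(hit[, 1])  # the later column of the worst pair
    step <- step + 1L
    warning("vif_filter: dropping '", names(x)[j],
            "' (perfectly collinear)", call. = FALSE)
    dropped <- rbind(dropped, data.frame(variable = names(x)[j], vif = Inf,
                                         step = step))
    x <- x[-j]
  }
  while (ncol(x) >= 2) {
    v <- vif(x)
    if (max(v) <= threshold) break
    j <- which.max(v)
    step <- step + 1L
    dropped <- rbind(dropped, data.frame(variable = names(x)[j],
                                         vif = unname(v[j]), step = step))
    x <- x[-j]
  }
  final <- if (ncol(x) >= 2) vif(x) else stats::setNames(rep(1, ncol(x)),
                                                         names(x))
  list(retained = names(x), dropped = dropped, vif = final)
}

#' Small-sample corrected AIC
#'
#' AICc = AIC + 2k(k+1)/(n-k-1); `Inf` when n <= k + 1.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# exact ML shape for a gamma sample with fitted means mu:
# solves n*(log k + 1 - digamma(k)) + sum(log(y/mu) - y/mu) = 0 in log k
gamma_shape_ml <- function(y, mu) {
  S <- sum(log(y / mu) - y / mu)
  n <- length(y)
  score <- function(lk) {
    k <- exp(lk)
    n * (log(k) + 1 - digamma(k)) + S
  }
  if (score(15) > 0) return(exp(15))  # essentially noise-free
  exp(stats::uniroot(score, c(-10, 15), tol = 1e-12)$root)
}

gamma_loglik <- function(y, mu, shape) {
  sum(stats::dgamma(y, shape = shape, rate = shape / mu, log = TRUE))
}

parse_random <- function(random) {
  if (is.null(random) || identical(random, "none")) return(NULL)
  if (identical(random, "intercept")) return("intercept")
  if (grepl("^intercept\\+", random))
    return(c("intercept", sub("^intercept\\+", "", random)))
  abort("random must be 'none', 'intercept' or 'intercept+<variable>'")
}

build_formula <- function(response, fixed, random, id) {
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  re <- parse_random(random)
  if (!is.null(re)) {
    rhs <- paste(rhs, sprintf("(1 | %s)", id), sep = " + ")
    slope <- setdiff(re, "intercept")
    if (length(slope)) {
      if (!slope %in% fixed)
        abort("random slope for '", slope, "' requires it among the fixed effects")
      rhs <- paste(rhs, sprintf("(0 + %s | %s)", slope, id), sep = " + ")
    }
  }
  stats::as.formula(paste(response, "~", rhs))
}

#' Fit a gamma growth model
#'
#' Gamma GLMM of a strictly positive response (BAI) with log link and
#' Gaussian per-tree random effects, maximising the Laplace-approximated
#' marginal likelihood via glmmTMB. Random slopes are modelled uncorrelated
#' with the random intercept (diagonal random-effect covariance), which
#' keeps boundary likelihood-ratio tests at one extra variance per slope.
#' Structures without random effects are fitted as a gamma GLM with an
#' exact maximum-likelihood shape profile, so log-likelihoods are
#' comparable across the whole model set.
#'
#' @param data Data frame of complete cases containing `response`, `id`
#'   and the (standardised) predictors.
#' @param fixed Character vector of fixed-effect predictor names (may be
#'   empty: intercept-only).
#' @param random `"none"`, `"intercept"`, or `"intercept+<variable>"` for an
#'   additional (uncorrelated) random slope; the slope variable must be in
#'   `fixed`.
#' @param response,id Column names of the response and the grouping factor.
#' @return Object of class `growth_fit`: coefficient table (`term`,
#'   `estimate`, `se`, `t`, `p`), random-effect variances, gamma shape,
#'   log-likelihood, parameter count `k`, `n`, `aicc`, fitted values and
#'   the model frame.
#' @export
fit_growth_model <- function(data, fixed = character(), random = "none",
                             response = "bai", id = "tree_id") {
  miss <- setdiff(c(response, id, fixed), names(data))
  if (length(miss)) abort("fit_growth_model: missing column(s): ",
                          paste(miss, collapse = ", "))
  y <- data[[response]]
  if (any(!is.finite(y)) || any(y <= 0))
    abort("fit_growth_model: response must be finite and > 0")
  fml <- build_formula(response, fixed, random, id)
  n <- nrow(data)

  if (is.null(parse_random(random))) {
    glm_fit <- stats::glm(fml, data = data,
                          family = stats::Gamma(link = "log"))
    mu <- as.numeric(stats::fitted(glm_fit))
    shape <- gamma_shape_ml(y, mu)
    ll <- gamma_loglik(y, mu, shape)
    k <- length(stats::coef(glm_fit)) + 1L  # betas + shape
    sm <- summary(glm_fit, dispersion = 1 / shape)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        se = sm[, 2], t = sm[, 3],
                        p = 2 * stats::pt(abs(sm[, 3]),
                                          df = n - (k - 1L),
                                          lower.tail = FALSE),
                        stringsAsFactors = FALSE)
    rownames(coefs) <- NULL
    fit <- structure(list(backend = "glm", model = glm_fit, formula = fml,
                          fixed = fixed, random = "none",
                          coefficients = coefs, ranef_var = numeric(0),
                          shape = shape, loglik = ll, k = k, n = n,
                          aicc = aicc(ll, k, n), fitted = mu,
                          response = response, id = id, data = data),
                     class = "growth_fit")
    return(fit)
  }

  warns <- character()
  m <- withCallingHandlers(
    glmmTMB::glmmTMB(fml, data = data,
                     family = stats::Gamma(link = "log")),
    warning = function(w) {
      # boundary fits (a variance at ~0) give a non-PD Hessian; keep the
      # fit and record the diagnostic instead of failing
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (isTRUE(m$fit$convergence != 0) || anyNA(m$fit$par))
    abort("fit_growth_model: glmmTMB did not converge (",
          m$fit$message %||% "no message", "); gradient norm ",
          signif(sqrt(sum(m$fit$objective^2)), 3))
  sm <- summary(m)$coefficients$cond
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], t = sm[, "z value"],
                      p = sm[, "Pr(>|z|)"], stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  vc <- glmmTMB::VarCorr(m)$cond
  ranef_var <- vapply(vc, function(v) as.numeric(v[1, 1]), numeric(1))
  re_terms <- parse_random(random)
  names(ranef_var) <- c("intercept", setdiff(re_terms, "intercept"))[
    seq_along(ranef_var)]
  ll_obj <- stats::logLik(m)
  ll <- as.numeric(ll_obj)
  # on the boundary glmmTMB reports NA logLik; the optimised objective is
  # still the maximised negative log-likelihood
  if (!is.finite(ll)) ll <- -m$fit$objective
  k <- attr(ll_obj, "df")
  shape <- glmmtmb_shape(m)
  fitted_mu <- stats::predict(m, type = "response")
  structure(list(backend = "glmmTMB", model = m, formula = fml,
                 fixed = fixed, random = random, coefficients = coefs,
                 ranef_var = ranef_var, shape = shape, loglik = ll, k = k,
                 n = n, aicc = aicc(ll, k, n),
                 fitted = as.numeric(fitted_mu),
                 response = response, id = id, data = data,
                 messages = warns),
            class = "growth_fit")
}

# glmmTMB's sigma() for the Gamma family returns the dispersion such that
# var(Y) = sigma^2 * mu^2, i.e. shape = 1 / sigma^2
glmmtmb_shape <- function(m) 1 / stats::sigma(m)^2

#' @export
print.growth_fit <- function(x, ...) {
  fml <- paste(gsub("\\s+", " ", deparse(x$formula)), collapse = " ")
  cat(sprintf("<growth_fit> %s | random: %s | n=%d k=%d logLik=%.2f AICc=%.2f\n",
              fml, x$random, x$n, x$k, x$loglik, x$aicc))
  print(x$coefficients, digits = 4)
  if (length(x$ranef_var)) {
    cat("random-effect SDs:",
        paste(names(x$ranef_var), round(sqrt(x$ranef_var), 4),
              sep = "=", collapse = "  "), "\n")
  }
  cat("gamma shape:", round(x$shape, 3), "\n")
  invisible(x)
}

#' Enumerate a crossed model set and select by AICc
#'
#' Fits every subset of the candidate fixed effects (up to `max_fixed`)
#' crossed with the requested random structures (a random slope structure
#' is only crossed with subsets containing its variable). Selection follows
#' the "best and most parsimonious" rule: among models within `delta` AICc
#' units of the minimum, the one with fewest parameters wins (ties broken
#' by lower AICc); `delta = 0` reduces to plain minimum-AICc selection.
#'
#' @param data Model data frame (standardised predictors).
#' @param candidates Character vector of candidate fixed effects (ideally
#'   already VIF-screened).
#' @param random_structures Character vector of random structures to cross
#'   (see [fit_growth_model()]).
#' @param max_fixed Cap on fixed-effect subset size (default 6).
#' @param delta AICc window for the parsimony rule (default 6).
#' @param response,id Passed to [fit_growth_model()].
#' @return List with `best` (the selected `growth_fit`), `table` (one row
#'   per fitted model, sorted by AICc) and `selected` (index into `table`).
#' @export
enumerate_and_select <- function(data, candidates,
                                 random_structures = "none",
                                 max_fixed = 6, delta = 6,
                                 response = "bai", id = "tree_id") {
  max_fixed <- min(max_fixed, length(candidates))
  subsets <- list(character(0))
  for (sz in seq_len(max_fixed))
    subsets <- c(subsets, utils::combn(candidates, sz, simplify = FALSE))
  rows <- list(); specs <- list()
  for (fx in subsets) {
    for (rs in random_structures) {
      slope <- setdiff(parse_random(rs), "intercept")
      if (length(slope) && !slope %in% fx) next
      fit <- tryCatch(fit_growth_model(data, fx, rs, response, id),
                      error = function(e) e)
      i <- length(rows) + 1L
      if (inherits(fit, "error")) {
        rows[[i]] <- data.frame(
          fixed = paste(fx, collapse = "+"), random = rs, k = NA_integer_,
          loglik = NA_real_, aicc = NA_real_, converged = FALSE,
          stringsAsFactors = FALSE)
        specs[[i]] <- list(fixed = fx, random = rs)
      } else {
        rows[[i]] <- data.frame(
          fixed = paste(fx, collapse = "+"), random = rs, k = fit$k,
          loglik = fit$loglik, aicc = fit$aicc, converged = TRUE,
          stringsAsFactors = FALSE)
        specs[[i]] <- list(fixed = fx, random = rs)
      }
    }
  }
  tab <- do.call(rbind, rows)
  ok <- which(tab$converged & is.finite(tab$aicc))
  if (!length(ok))
    abort("enumerate_and_select: no model converged (",
          sum(!tab$converged), " failures)")
  amin <- min(tab$aicc[ok])
  eligible <- ok[tab$aicc[ok] <= amin + delta]
  sel <- eligible[order(tab$k[eligible], tab$aicc[eligible])][1]
  best <- fit_growth_model(data, specs[[sel]]$fixed, specs[[sel]]$random,
                           response, id)
  ord <- order(tab$aicc)
  tab$delta_aicc <- tab$aicc - amin
  tab$selected <- seq_len(nrow(tab)) == sel
  list(best = best, table = tab[ord, ], selected = which(ord == sel))
}

pchisq_upper <- function(x, df) {
  if (df == 0) return(as.numeric(x <= 1e-12))
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Likelihood ratio test for random effects
#'
#' Compares two fits with identical fixed effects whose random structures
#' are nested. Because the null puts variances on the boundary of the
#' parameter space, the reference distribution is the equal-weight mixture
#' of chi-squared distributions with d-1 and d degrees of freedom, where d
#' is the difference in parameter count (the 50:50 chi2_0/chi2_1 mixture
#' for one extra variance).
#'
#' @param full,reduced `growth_fit` objects.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt_random <- function(full, reduced) {
  if (!setequal(full$fixed, reduced$fixed))
    abort("lrt_random: fixed effects differ")
  rank_of <- function(r) length(parse_random(r))  # 0, 1 or 2 terms
  if (rank_of(full$random) < rank_of(reduced$random))
    abort("lrt_random: 'reduced' is not nested in 'full'")
  red_terms <- parse_random(reduced$random)
  full_terms <- parse_random(full$random)
  if (!all(red_terms %in% full_terms))
    abort("lrt_random: random structures are not nested")
  d <- full$k - reduced$k
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (d == 0) 1
  else 0.5 * pchisq_upper(stat, d - 1) + 0.5 * pchisq_upper(stat, d)
  list(statistic = stat, df = d, p_value = p)
}

#' Predictive skill of a fitted growth model
#'
#' Three complementary summaries: (i) marginal variance explained on the
#' link scale, var(X beta) / (var(X beta) + sum of random-effect variances
#' + trigamma(shape)), using the gamma log-scale residual variance; (ii)
#' adjusted R^2 of observed on predicted values per observation; (iii)
#' Pearson correlation between the observed and predicted year-mean
#' chronologies with a 99% significance flag, plus a 95% prediction band
#' for the year means from parametric simulation of the fitted gamma
#' model. A constant prediction (intercept-only model) yields `NA`
#' chronology correlation.
#'
#' @param fit A `growth_fit`.
#' @param nsim Number of parametric simulations for the band.
#' @param seed Seed for the simulation stream.
#' @return List with `marginal_r2`, `adj_r2`, `chron_r`, `chron_p`,
#'   `chron_sig99`, `band` (data frame `year`, `observed`, `predicted`,
#'   `lower`, `upper`).
#' @export
predictive_skill <- function(fit, nsim = 200, seed = 1) {
  data <- fit$data
  obs <- data[[fit$response]]
  pred <- fit$fitted
  X <- stats::model.matrix(
    stats::reformulate(if (length(fit$fixed)) fit$fixed else "1"), data)
  beta <- fit$coefficients$estimate[match(colnames(X),
                                          fit$coefficients$term)]
  eta_fixed <- as.numeric(X %*% beta)
  vf <- stats::var(eta_fixed)
  vr <- sum(fit$ranef_var)
  marginal_r2 <- vf / (vf + vr + trigamma(fit$shape))
  adj_r2 <- if (stats::sd(pred) < 1e-12) NA_real_
  else suppressWarnings(summary(stats::lm(obs ~ pred)))$adj.r.squared
  yrs <- data$year
  chron_obs <- tapply(obs, yrs, mean)
  chron_pred <- tapply(pred, yrs, mean)
  if (stats::sd(chron_pred) < 1e-12) {
    chron_r <- NA_real_; chron_p <- NA_real_; sig99 <- NA
  } else {
    chron_r <- stats::cor(chron_obs, chron_pred)
    chron_p <- cor_p_value(chron_r, length(chron_obs))
    sig99 <- chron_p < 0.01
  }
  sims <- with_seed(seed, {
    vapply(seq_len(nsim), function(i) {
      ysim <- stats::rgamma(length(pred), shape = fit$shape,
                            rate = fit$shape / pred)
      tapply(ysim, yrs, mean)
    }, numeric(length(chron_obs)))
  })
  band <- data.frame(year = as.integer(names(chron_obs)),
                     observed = as.numeric(chron_obs),
                     predicted = as.numeric(chron_pred),
                     lower = apply(sims, 1, stats::quantile, 0.025),
                     upper = apply(sims, 1, stats::quantile, 0.975))
  rownames(band) <- NULL
  list(marginal_r2 = marginal_r2, adj_r2 = adj_r2, chron_r = chron_r,
       chron_p = chron_p, chron_sig99 = sig99, band = band)
}

#' Assemble the growth-model data set
#'
#' Joins per-tree BAI, the group iWUE chronology (trees without isotope
#' measurements take their group's chronology value), seasonal climate
#' predictors and tree metadata, restricted to one analysis window, and
#' standardises every predictor: seasonal predictors and iWUE as z-scores
#' of their window-year values (iWUE within group, whose chronologies have
#' group-specific level and trend), tree size variables as z-scores across
#' trees. Lagged predictors are lagged before standardisation (the lag
#' columns of [seasonal_aggregate()] are built from the full record).
#'
#' @param bai Long data frame `tree_id`, `group`, `year`, `bai`.
#' @param meta Tree metadata (`tree_id`, `group`, `dbh`, `height`).
#' @param seasonal Output of [seasonal_aggregate()].
#' @param iwue_group Data frame `group`, `year`, `iwue` (group chronologies).
#' @param window Year range `c(first, last)`.
#' @return Data frame with response `bai`, grouping `tree_id`, `group`,
#'   `year`, and standardised predictors `iwue`, `dbh`, `height` and the 16
#'   seasonal columns; scaling constants in attribute `"scaling"`.
#' @export
build_model_data <- function(bai, meta, seasonal, iwue_group, window) {
  d <- bai[window_years(bai$year, window), , drop = FALSE]
  if (!nrow(d)) abort("build_model_data: no BAI rows in window")
  d$iwue <- iwue_group$iwue[match(paste(d$group, d$year),
                                  paste(iwue_group$group, iwue_group$year))]
  idx <- match(d$tree_id, meta$tree_id)
  d$dbh <- meta$dbh[idx]
  d$height <- meta$height[idx]
  scaling <- list()
  # seasonal predictors: z-scores over the window years
  syr <- seasonal[window_years(seasonal$year, window), , drop = FALSE]
  for (pn in seasonal_predictors()) {
    m <- mean(syr[[pn]], na.rm = TRUE); s <- stats::sd(syr[[pn]], na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    d[[pn]] <- (seasonal[[pn]][match(d$year, seasonal$year)] - m) / s
    scaling[[pn]] <- c(mean = m, sd = s)
  }
  # iWUE: z-scores within group over the window years
  for (gr in unique(d$group)) {
    gi <- iwue_group[iwue_group$group == gr &
                       window_years(iwue_group$year, window), ]
    m <- mean(gi$iwue, na.rm = TRUE); s <- stats::sd(gi$iwue, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    sel <- d$group == gr
    d$iwue[sel] <- (d$iwue[sel] - m) / s
    scaling[[paste0("iwue.", gr)]] <- c(mean = m, sd = s)
  }
  # tree size: z-scores across trees
  for (pn in c("dbh", "height")) {
    tv <- meta[[pn]][match(unique(d$tree_id), meta$tree_id)]
    m <- mean(tv); s <- stats::sd(tv)
    if (!is.finite(s) || s == 0) s <- 1
    d[[pn]] <- (d[[pn]] - m) / s
    scaling[[pn]] <- c(mean = m, sd = s)
  }
  d <- d[stats::complete.cases(d), , drop = FALSE]
  attr(d, "scaling") <- scaling
  d
}
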