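# Independent brute-force oracles used to freeze expected values. These
# deliberately avoid the package's own code paths.

# cumulative disc-area BAI: literal geometry, year by year
oracle_bai <- function(widths, r0 = 0) {
  out <- numeric(length(widths))
  r_prev <- r0
  for (i in seq_along(widths)) {
    r_now <- r_prev + widths[i]
    out[i] <- pi * r_now^2 - pi * r_prev^2
    r_prev <- r_now
  }
  out
}

# mean pairwise Pearson correlation via an explicit double loop
oracle_mean_r <- function(mat, min_overlap = 3) {
  ids <- colnames(mat)
  rs <- c()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    ok <- !is.na(mat[, i]) & !is.na(mat[, j])
    if (sum(ok) < min_overlap) next
    rs <- c(rs, cor(mat[ok, i], mat[ok, j]))
  }
  mean(rs)
}

# Kruskal-Wallis H from the explicit rank-sum formula with tie correction
oracle_kw_H <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  rk <- rank(x)
  Ri <- tapply(rk, g, sum)
  ni <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}

# exact permutation p-value for Kruskal-Wallis (small pooled n only)
oracle_kw_perm_p <- function(x, g) {
  g <- factor(g)
  H_obs <- oracle_kw_H(x, g)
  perms <- gtools_permute_groups(length(x), tabulate(g))
  Hs <- vapply(perms, function(idx) {
    oracle_kw_H(x, rep(seq_along(tabulate(g)), tabulate(g))[order(idx)])
  }, numeric(1))
  mean(Hs >= H_obs - 1e-12)
}

# all distinct assignments of n items to groups of given sizes, as
# permutations of 1..n (uses combn recursively; fine for n <= 10)
gtools_permute_groups <- function(n, sizes) {
  out <- list()
  assign_rec <- function(remaining, sizes_left, acc) {
    if (!length(sizes_left)) {
      out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    ch <- combn(remaining, sizes_left[1], simplify = FALSE)
    for (s in ch) assign_rec(setdiff(remaining, s), sizes_left[-1],
                             c(acc, s))
  }
  assign_rec(seq_len(n), sizes, integer(0))
  out
}

# VIF via explicit auxiliary least-squares regressions
oracle_vif <- function(x) {
  x <- as.data.frame(x)
  vapply(seq_along(x), function(j) {
    fit <- lm(x[[j]] ~ ., data = x[-j])
    r2 <- summary(fit)$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

# direct ML fit of a gamma GLM with log link: joint optimisation over
# coefficients and log shape (independent of stats::glm / glmmTMB)
oracle_gamma_glm <- function(X, y) {
  nll <- function(par) {
    beta <- par[-length(par)]
    shape <- exp(par[length(par)])
    mu <- exp(as.numeric(X %*% beta))
    -sum(dgamma(y, shape = shape, rate = shape / mu, log = TRUE))
  }
  start <- c(solve(crossprod(X), crossprod(X, log(y))), 0)
  fit <- suppressWarnings(  # optim may probe extreme shapes
    optim(start, nll, method = "BFGS",
          control = list(maxit = 1000, reltol = 1e-14)))
  list(beta = fit$par[-length(fit$par)],
       shape = exp(fit$par[length(fit$par)]),
       loglik = -fit$value)
}

# small long-format series builder
long_series <- function(tree_id, years, values, group = "QuPe") {
  data.frame(tree_id = tree_id, group = group, year = years, value = values,
             stringsAsFactors = FALSE)
}

# monthly climate frame with constant values
flat_climate <- function(years, tmean = 10, psum = 30) {
  expand.grid(month = 1:12, year = years)[, c("year", "month")] |>
    transform(tmean = tmean, psum = psum)
}
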