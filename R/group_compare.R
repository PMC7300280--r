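# Nonparametric comparison of genetic groups and of subperiods: the
# Kruskal-Wallis omnibus test, the Nemenyi post hoc on mean ranks with a
# studentized-range reference, significance letters, and per-tree period
# anomalies with paired tests.

#' Kruskal-Wallis rank test
#'
#' Tie-corrected rank-based omnibus test for k independent samples, with p
#' from the chi-squared approximation (k - 1 df). Degenerate input where
#' every pooled value is identical returns H = 0, p = 1.
#'
#' @param x Numeric values.
#' @param g Group labels, same length as `x`.
#' @return List with `statistic` (H), `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(x, g) {
  g <- factor(g)
  if (length(x) != length(g)) abort("kruskal_wallis: length mismatch")
  if (nlevels(g) < 2) abort("kruskal_wallis needs >= 2 groups")
  if (length(x) < 3) abort("kruskal_wallis needs total n >= 3")
  if (length(unique(x)) == 1L)
    return(list(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                n = length(x)))
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = length(x))
}

#' Nemenyi pairwise post hoc test
#'
#' All-pairs comparison of mean ranks after a Kruskal-Wallis omnibus,
#' using the studentized-range reference distribution (tie-corrected
#' variance; the standard large-sample variant for unequal group sizes).
#' Decisions at `alpha` are translated into significance letters: groups
#' sharing a letter are not significantly different.
#'
#' @param x Numeric values.
#' @param g Group labels.
#' @param alpha Level for the letter display (default 0.05).
#' @return List of class `nemenyi` with `p_matrix`, `statistic`,
#'   `mean_ranks`, `letters`, `alpha`.
#' @export
nemenyi_pairwise <- function(x, g, alpha = 0.05) {
  if (is.factor(g) && any(table(g) == 0))
    abort("nemenyi_pairwise: empty group")
  g <- factor(g)
  if (nlevels(g) < 2) abort("nemenyi_pairwise needs >= 2 groups")
  k <- nlevels(g)
  N <- length(x)
  rk <- rank(x)
  mean_ranks <- tapply(rk, g, mean)
  n_i <- tabulate(g)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  var_unit <- C * N * (N + 1) / 12
  stat <- p <- matrix(NA_real_, k, k, dimnames = list(levels(g), levels(g)))
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(var_unit * (1 / n_i[i] + 1 / n_i[j]))
    q <- abs(mean_ranks[i] - mean_ranks[j]) / se
    stat[i, j] <- stat[j, i] <- q
    p[i, j] <- p[j, i] <- stats::ptukey(q * sqrt(2), nmeans = k, df = Inf,
                                        lower.tail = FALSE)
  }
  diag(p) <- 1
  diag(stat) <- 0
  structure(list(p_matrix = p, statistic = stat,
                 mean_ranks = as.numeric(mean_ranks),
                 letters = significance_letters(p, alpha,
                                                order_by = mean_ranks),
                 alpha = alpha),
            class = "nemenyi")
}

# Letters from a symmetric p-value matrix: maximal cliques of the
# "not significantly different" graph, ordered by group means, lettered
# a, b, c, ... Works for small k (subset enumeration).
significance_letters <- function(p_matrix, alpha = 0.05, order_by = NULL) {
  k <- nrow(p_matrix)
  labs <- rownames(p_matrix)
  nsd <- p_matrix >= alpha
  diag(nsd) <- TRUE
  if (k > 15) abort("significance letters supported for up to 15 groups")
  subsets <- list()
  for (code in 1:(2^k - 1)) {
    idx <- which(bitwAnd(code, 2^(0:(k - 1))) > 0)
    if (all(nsd[idx, idx])) subsets[[length(subsets) + 1]] <- idx
  }
  maximal <- Filter(function(s) {
    !any(vapply(subsets, function(t)
      length(t) > length(s) && all(s %in% t), logical(1)))
  }, subsets)
  ord <- if (!is.null(order_by)) order(vapply(maximal, function(s)
    min(order_by[s]), numeric(1))) else seq_along(maximal)
  maximal <- maximal[ord]
  letters_out <- stats::setNames(rep("", k), labs)
  for (ci in seq_along(maximal))
    for (i in maximal[[ci]])
      letters_out[i] <- paste0(letters_out[i], letters[ci])
  letters_out
}

#' @export
print.nemenyi <- function(x, ...) {
  cat("<nemenyi> pairwise p-values:\n")
  print(round(x$p_matrix, 4))
  cat("letters (alpha=", x$alpha, "): ",
      paste(names(x$letters), x$letters, sep = "=", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Omnibus + post hoc group comparison
#'
#' Convenience wrapper running [kruskal_wallis()] and [nemenyi_pairwise()]
#' on the same data.
#'
#' @inheritParams nemenyi_pairwise
#' @return List of class `group_comparison` with `kruskal` and `nemenyi`.
#' @export
compare_groups <- function(x, g, alpha = 0.05) {
  structure(list(kruskal = kruskal_wallis(x, g),
                 nemenyi = nemenyi_pairwise(x, g, alpha)),
            class = "group_comparison")
}

#' Per-tree subperiod anomalies with group tests
#'
#' The experimental unit is the tree: for each tree the mean of the
#' variable over each window is computed and the anomaly is
#' mean(period2) - mean(period1). Trees missing either window are excluded
#' with a message. Within each group the anomaly is tested against zero by
#' the paired Wilcoxon signed-rank test (flags at 0.05 and 0.01); between
#' groups the anomalies are compared with Kruskal-Wallis + Nemenyi.
#'
#' @param x Long data frame `tree_id`, `group`, `year`, value column.
#' @param window1,window2 Year ranges `c(first, last)`.
#' @param value Name of the value column (default: last column).
#' @param min_years Minimum years required per tree and window (default 5).
#' @return List with `trees` (per-tree means and anomaly), `within`
#'   (per-group Wilcoxon results) and `between` (`group_comparison` of the
#'   anomalies, `NULL` if < 2 groups).
#' @export
period_difference <- function(x, window1, window2, value = NULL,
                              min_years = 5) {
  value <- value %||% names(x)[ncol(x)]
  per_tree <- lapply(split(x, x$tree_id), function(d) {
    v1 <- d[[value]][window_years(d$year, window1)]
    v2 <- d[[value]][window_years(d$year, window2)]
    if (sum(!is.na(v1)) < min_years || sum(!is.na(v2)) < min_years) {
      message("period_difference: excluding tree ", d$tree_id[1],
              " (insufficient coverage of both windows)")
      return(NULL)
    }
    data.frame(tree_id = d$tree_id[1], group = d$group[1],
               mean1 = mean(v1, na.rm = TRUE), mean2 = mean(v2, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  trees <- do.call(rbind, per_tree)
  if (is.null(trees) || !nrow(trees))
    abort("period_difference: no tree covers both windows")
  rownames(trees) <- NULL
  trees$anomaly <- trees$mean2 - trees$mean1
  within <- do.call(rbind, lapply(split(trees, trees$group), function(d) {
    if (nrow(d) < 2 || all(d$anomaly == 0)) {
      p <- if (all(d$anomaly == 0)) 1 else NA_real_
      return(data.frame(group = d$group[1], n = nrow(d), V = NA_real_, p = p,
                        mean_anomaly = mean(d$anomaly),
                        sig95 = isTRUE(p < 0.05), sig99 = isTRUE(p < 0.01),
                        stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(d$mean2, d$mean1,
                                              paired = TRUE, exact = FALSE))
    data.frame(group = d$group[1], n = nrow(d), V = unname(wt$statistic),
               p = wt$p.value, mean_anomaly = mean(d$anomaly),
               sig95 = wt$p.value < 0.05, sig99 = wt$p.value < 0.01,
               stringsAsFactors = FALSE)
  }))
  rownames(within) <- NULL
  between <- if (length(unique(trees$group)) >= 2)
    compare_groups(trees$anomaly, trees$group) else NULL
  list(trees = trees, within = within, between = between)
}
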