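# Basal area increment conversion, group chronologies and their quality
# statistics (mean interseries correlation, expressed population signal),
# linear trends, high-pass filtering and chronology cross-correlation.

#' Convert ring widths to basal area increments
#'
#' BAI(t) = pi * (r_t^2 - r_{t-1}^2) with r_t the cumulative radius through
#' year t. Removes the geometric age trend of raw ring widths: a constant
#' ring width yields a strictly increasing BAI. The sum of BAI over the
#' series equals pi * (r_final^2 - r_initial^2) exactly.
#'
#' @param series A [ring_series()].
#' @param initial_radius Radius (mm) already accumulated before the first
#'   ring (bark/missing-pith offset); defaults to 0 (pith reached).
#' @return A data frame `tree_id`, `year`, `bai` (mm^2/yr).
#' @export
bai_from_widths <- function(series, initial_radius = 0) {
  if (!inherits(series, "ring_series")) abort("series must be a ring_series")
  if (initial_radius < 0) abort("initial_radius must be >= 0")
  if (any(series$widths < 0)) abort("ring widths must be >= 0")
  r <- initial_radius + cumsum(series$widths)
  r_prev <- c(initial_radius, r[-length(r)])
  data.frame(tree_id = series$tree_id, year = series_years(series),
             bai = pi * (r^2 - r_prev^2), stringsAsFactors = FALSE)
}

#' BAI for a collection of trees
#'
#' Applies [bai_from_widths()] to every series; when several cores share a
#' tree (ids differing only by a trailing core letter are *not* merged here
#' -- merge cores to tree level before calling, see [merge_cores()]).
#'
#' @param rings List of [ring_series()].
#' @param meta Optional metadata; adds a `group` column.
#' @param initial_radius Passed to [bai_from_widths()].
#' @return Long data frame `tree_id`, (`group`,) `year`, `bai`.
#' @export
bai_all <- function(rings, meta = NULL, initial_radius = 0) {
  out <- do.call(rbind, lapply(rings, bai_from_widths,
                               initial_radius = initial_radius))
  rownames(out) <- NULL
  if (!is.null(meta))
    out$group <- meta$group[match(out$tree_id, meta$tree_id)]
  out
}

#' Average multiple cores to one tree-level width series
#'
#' Cores of the same tree are averaged year-wise into a single ring-width
#' series before BAI conversion, so that all downstream analyses are per
#' tree.
#'
#' @param rings List of [ring_series()] (core-level).
#' @param tree_of Named character vector mapping core id to tree id; by
#'   default ids are already tree-level and returned unchanged.
#' @return List of tree-level [ring_series()].
#' @export
merge_cores <- function(rings, tree_of = NULL) {
  if (is.null(tree_of)) return(rings)
  long <- rwl_to_long(rings)
  long$tree <- tree_of[long$tree_id]
  if (anyNA(long$tree)) abort("merge_cores: unmapped core id(s)")
  out <- lapply(split(long, long$tree), function(d) {
    m <- tapply(d$width_mm, d$year, mean)
    yrs <- as.integer(names(m))
    if (any(diff(yrs) != 1L))
      abort("merge_cores: cores of tree '", d$tree[1],
            "' do not form consecutive years")
    ring_series(d$tree[1], yrs[1], as.numeric(m))
  })
  out[order(names(out))]
}

#' Mean interseries correlation
#'
#' Average of all pairwise Pearson correlations between member series over
#' their common years (pairs with fewer than 3 overlapping years are
#' skipped), optionally restricted to a window.
#'
#' @param members Long data frame `tree_id`, `year`, and a value column.
#' @param window Optional year range `c(first, last)`.
#' @param value Name of the value column (default the third column).
#' @return The mean pairwise correlation (scalar).
#' @export
mean_interseries_r <- function(members, window = NULL, value = NULL) {
  value <- value %||% setdiff(names(members), c("tree_id", "year", "group"))[1]
  keep <- window_years(members$year, window)
  members <- members[keep, , drop = FALSE]
  ids <- unique(members$tree_id)
  if (length(ids) < 2L)
    abort("mean_interseries_r needs at least two member series")
  yrs <- sort(unique(members$year))
  mat <- matrix(NA_real_, length(yrs), length(ids),
                dimnames = list(yrs, ids))
  mat[cbind(match(members$year, yrs), match(members$tree_id, ids))] <-
    members[[value]]
  pr <- utils::combn(length(ids), 2)
  rs <- apply(pr, 2, function(ij) {
    a <- mat[, ij[1]]; b <- mat[, ij[2]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3L) return(NA_real_)
    suppressWarnings(stats::cor(a[ok], b[ok]))
  })
  rs <- rs[!is.na(rs)]
  if (!length(rs))
    abort("mean_interseries_r: no pair of series overlaps by >= 3 years")
  mean(rs)
}

#' Expressed population signal
#'
#' EPS = n * rbar / (n * rbar + (1 - rbar)) (Wigley et al. formulation).
#' Chronologies with EPS > 0.85 are conventionally considered reliable.
#' If the denominator is not positive the statistic is undefined; `NA` is
#' returned with a warning (treated as not reliable).
#'
#' @param rbar Mean interseries correlation, in (-1, 1].
#' @param n Number of member series (>= 2).
#' @return EPS in `[0, 1]` (vectorised over `rbar` and `n`).
#' @export
eps <- function(rbar, n) {
  if (any(n < 2)) abort("eps: n must be >= 2")
  if (any(rbar <= -1 | rbar > 1)) abort("eps: rbar must be in (-1, 1]")
  den <- n * rbar + (1 - rbar)
  out <- ifelse(den > 0, n * rbar / den, NA_real_)
  if (anyNA(out))
    warning("eps undefined (n*rbar + (1-rbar) <= 0); returning NA (not reliable)",
            call. = FALSE)
  out
}

#' Build a group-level chronology
#'
#' Per-year arithmetic mean over the members available that year, with
#' sample depth, the window-wide mean interseries correlation, EPS, and the
#' reliable span (years whose running EPS -- window-wide rbar with the
#' year's sample depth -- exceeds 0.85).
#'
#' @param members Long data frame `tree_id`, `year`, value column.
#' @param variable One of `"BAI"`, `"d13C"`, `"iWUE"` (label only).
#' @param group Optional group label.
#' @param window Optional year range restricting the chronology.
#' @param value Name of the value column (default: third column).
#' @return An object of class `chronology` with elements `series`
#'   (data frame `year`, `mean`, `depth`), `members`, `rbar`, `eps`,
#'   `reliable_span`, `n_trees`.
#' @export
build_chronology <- function(members, variable = c("BAI", "d13C", "iWUE"),
                             group = NA_character_, window = NULL,
                             value = NULL) {
  variable <- match.arg(variable)
  value <- value %||% setdiff(names(members), c("tree_id", "year", "group"))[1]
  keep <- window_years(members$year, window)
  members <- members[keep, , drop = FALSE]
  if (!nrow(members)) abort("build_chronology: no member data")
  yrs <- sort(unique(members$year))
  mean_v <- tapply(members[[value]], members$year, mean)
  depth <- tapply(members[[value]], members$year, length)
  n_trees <- length(unique(members$tree_id))
  rbar <- if (n_trees >= 2L)
    tryCatch(mean_interseries_r(members, value = value),
             error = function(e) NA_real_)
  else NA_real_
  eps_total <- if (!is.na(rbar) && rbar > -1 && rbar <= 1 && n_trees >= 2)
    suppressWarnings(eps(rbar, n_trees)) else NA_real_
  running_eps <- rep(NA_real_, length(yrs))
  if (!is.na(rbar) && rbar > -1 && rbar <= 1) {
    ok <- depth >= 2
    running_eps[ok] <- suppressWarnings(eps(rbar, depth[ok]))
  }
  reliable <- !is.na(running_eps) & running_eps > 0.85
  reliable_span <- if (any(reliable)) range(yrs[reliable]) else c(NA, NA)
  structure(
    list(variable = variable, group = group,
         series = data.frame(year = yrs, mean = as.numeric(mean_v),
                             depth = as.integer(depth)),
         members = members, value = value, n_trees = n_trees,
         rbar = rbar, eps = eps_total,
         running_eps = running_eps, reliable_span = reliable_span),
    class = "chronology")
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf(
    "<chronology> %s%s: %d trees, %d-%d, rbar=%.3f, EPS=%.3f, reliable %s-%s\n",
    x$variable, if (!is.na(x$group)) paste0(" [", x$group, "]") else "",
    x$n_trees, min(x$series$year), max(x$series$year),
    x$rbar, x$eps, x$reliable_span[1], x$reliable_span[2]))
  invisible(x)
}

chron_values <- function(x) {
  if (inherits(x, "chronology"))
    data.frame(year = x$series$year, value = x$series$mean)
  else {
    stopifnot(is.data.frame(x), ncol(x) >= 2)
    stats::setNames(x[, 1:2], c("year", "value"))
  }
}

#' Least-squares linear trend of an annual series
#'
#' OLS slope of value on calendar year with a two-sided t test.
#'
#' @param x A `chronology` or a data frame `year`, `value`.
#' @param window Optional year range.
#' @param alpha Significance level (default 0.05).
#' @return List with `slope` (units/yr), `intercept`, `se`, `t`, `p`, `n`,
#'   `significant`.
#' @export
linear_trend <- function(x, window = NULL, alpha = 0.05) {
  d <- chron_values(x)
  d <- d[window_years(d$year, window) & !is.na(d$value), , drop = FALSE]
  if (nrow(d) < 3) abort("linear_trend needs >= 3 points")
  if (length(unique(d$year)) < 2) abort("linear_trend: constant year vector")
  fit <- stats::lm(value ~ year, data = d)
  sm <- suppressWarnings(summary(fit))$coefficients  # tolerate exact fits
  list(slope = unname(sm["year", "Estimate"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       se = unname(sm["year", "Std. Error"]),
       t = unname(sm["year", "t value"]),
       p = unname(sm["year", "Pr(>|t|)"]),
       n = nrow(d),
       significant = unname(sm["year", "Pr(>|t|)"] < alpha))
}

#' High-pass filter by a centered moving average
#'
#' Subtracts a centered moving average of even order `window` (the classic
#' symmetric filter with half weights at both ends, so a pure linear trend
#' is removed exactly). Edge years where the full window does not fit are
#' returned as `NA`.
#'
#' @param values Numeric vector (regular annual spacing assumed).
#' @param window Filter length in years (default 10).
#' @return Filtered vector, same length, `NA` at the edges.
#' @export
highpass <- function(values, window = 10) {
  n <- length(values)
  if (window > n) abort("highpass: window exceeds series length")
  if (window %% 2 == 0) {
    w <- c(0.5, rep(1, window - 1), 0.5) / window
  } else {
    w <- rep(1, window) / window
  }
  ma <- stats::filter(values, w, sides = 2)
  as.numeric(values - ma)
}

#' Smoothing spline with a fixed frequency cutoff
#'
#' Discrete smoothing spline (second-difference penalty) whose frequency
#' response is 50% at the requested wavelength: the penalty weight is
#' lambda = (2 sin(pi / wavelength))^-4, giving the transfer function
#' H(omega) = 1 / (1 + lambda (2 sin(omega/2))^4). Used for the "n-year
#' spline" smoothing of chronologies before climate screens.
#'
#' @param values Numeric vector without missing values.
#' @param wavelength Wavelength (years) of 50% frequency response.
#' @return The smoothed series (low-pass component).
#' @export
spline_smooth <- function(values, wavelength = 10) {
  n <- length(values)
  if (anyNA(values)) abort("spline_smooth: missing values not allowed")
  if (n < 4) abort("spline_smooth needs >= 4 points")
  lambda <- (2 * sin(pi / wavelength))^-4
  D <- diff(diag(n), differences = 2)
  as.numeric(solve(diag(n) + lambda * crossprod(D), values))
}

#' Correlation between two chronologies
#'
#' Pearson correlation over common years, optionally on 10-yr high-pass
#' filtered versions, with t-based p value and 95%/99% significance flags.
#'
#' @param a,b `chronology` objects or data frames `year`, `value`.
#' @param window Optional year range.
#' @param filtered If `TRUE`, high-pass filter both series first.
#' @param filter_window Moving-average length for the filter.
#' @return List with `r`, `n`, `p`, `sig95`, `sig99`, `filtered`.
#' @export
chronology_correlation <- function(a, b, window = NULL, filtered = FALSE,
                                   filter_window = 10) {
  da <- chron_values(a); db <- chron_values(b)
  da <- da[window_years(da$year, window), ]
  db <- db[window_years(db$year, window), ]
  yrs <- intersect(da$year, db$year)
  va <- da$value[match(yrs, da$year)]
  vb <- db$value[match(yrs, db$year)]
  if (filtered) {
    va <- highpass(va, filter_window)
    vb <- highpass(vb, filter_window)
  }
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 10) abort("chronology_correlation: fewer than 10 common years")
  r <- stats::cor(va[ok], vb[ok])
  n <- sum(ok)
  p <- cor_p_value(r, n)
  list(r = r, n = n, p = p, sig95 = p < 0.05, sig99 = p < 0.01,
       filtered = filtered)
}
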