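# Homogenisation of monthly climate records, seasonal aggregation into
# lagged predictors, and the climate-chronology correlation screen.

SEASONS <- list(Wi = c(12L, 1L, 2L), Sp = 3:5, Su = 6:8, Au = 9:11)

#' Merge a long distant record into a short local one
#'
#' Per calendar month over the overlap years, temperature of the long
#' record is shifted additively to the local mean and precipitation scaled
#' multiplicatively; local values are kept verbatim where available, the
#' adjusted long record fills the rest. If a month's long-record
#' precipitation mean is zero the adjustment falls back to an additive
#' shift with a warning. The merged record's overlap-period monthly means
#' equal the local record's, and the operation is idempotent on
#' already-merged records.
#'
#' @param long Monthly climate data frame (`year`, `month`, `tmean`, `psum`)
#'   from the long, distant station.
#' @param target Monthly climate data frame from the short local station.
#' @return Merged monthly climate data frame with a `source` column
#'   (`"target"` or `"long_rescaled"`).
#' @export
rescale_long_record <- function(long, target) {
  overlap <- intersect(unique(long$year), unique(target$year))
  if (length(overlap) < 10)
    abort("rescale_long_record: fewer than 10 overlapping years")
  t_off <- numeric(12); p_ratio <- numeric(12)
  for (m in 1:12) {
    lt <- long[long$month == m & long$year %in% overlap, ]
    tt <- target[target$month == m & target$year %in% overlap, ]
    if (!nrow(lt) || !nrow(tt))
      abort("rescale_long_record: month ", m, " absent from overlap")
    t_off[m] <- mean(tt$tmean) - mean(lt$tmean)
    if (mean(lt$psum) > 0) {
      p_ratio[m] <- mean(tt$psum) / mean(lt$psum)
    } else {
      warning("rescale_long_record: zero precipitation mean for month ", m,
              " in long record; using additive shift", call. = FALSE)
      p_ratio[m] <- NA_real_  # additive fallback marker
    }
  }
  adj <- long
  adj$tmean <- long$tmean + t_off[long$month]
  add_p <- is.na(p_ratio[long$month])
  adj$psum <- ifelse(add_p, long$psum, long$psum * p_ratio[long$month])
  if (any(add_p)) {
    p_off <- vapply(1:12, function(m) {
      tt <- target[target$month == m & target$year %in% overlap, ]
      lt <- long[long$month == m & long$year %in% overlap, ]
      mean(tt$psum) - mean(lt$psum)
    }, numeric(1))
    adj$psum[add_p] <- pmax(0, long$psum[add_p] + p_off[long$month[add_p]])
  }
  key_t <- paste(target$year, target$month)
  key_a <- paste(adj$year, adj$month)
  fill <- adj[!(key_a %in% key_t), , drop = FALSE]
  out <- rbind(
    cbind(target[, c("year", "month", "tmean", "psum")], source = "target",
          stringsAsFactors = FALSE),
    cbind(fill[, c("year", "month", "tmean", "psum")],
          source = "long_rescaled", stringsAsFactors = FALSE))
  out <- out[order(out$year, out$month), ]
  rownames(out) <- NULL
  out
}

#' Seasonal climate predictors with one-year lags
#'
#' Aggregates a monthly record into the 16 seasonal predictors used by the
#' climate screens and the growth model: winter (DJF), spring (MAM), summer
#' (JJA) and autumn (SON) temperature means and precipitation sums for the
#' current year (columns `WiT`, `SpT`, `SuT`, `AuT`, `WiP`, `SpP`, `SuP`,
#' `AuP`) and the previous year (same names with suffix `t`, e.g. `SuTt`).
#' Winter of year y uses December of y-1 with January/February of y. A
#' season with any missing month is `NA` for that year.
#'
#' @param monthly Monthly climate data frame (`year`, `month`, `tmean`,
#'   `psum`).
#' @return Data frame with `year` and 16 predictor columns.
#' @export
seasonal_aggregate <- function(monthly) {
  yrs <- sort(unique(monthly$year))
  key <- paste(monthly$year, monthly$month)
  get_val <- function(y, m, var) {
    i <- match(paste(y, m), key)
    if (is.na(i)) NA_real_ else monthly[[var]][i]
  }
  out <- data.frame(year = yrs)
  for (sn in names(SEASONS)) {
    months <- SEASONS[[sn]]
    tvals <- pvals <- rep(NA_real_, length(yrs))
    for (k in seq_along(yrs)) {
      y <- yrs[k]
      ys <- ifelse(months == 12L, y - 1L, y)
      tm <- mapply(get_val, ys, months, MoreArgs = list(var = "tmean"))
      pm <- mapply(get_val, ys, months, MoreArgs = list(var = "psum"))
      if (!anyNA(tm)) tvals[k] <- mean(tm)
      if (!anyNA(pm)) pvals[k] <- sum(pm)
    }
    out[[paste0(sn, "T")]] <- tvals
    out[[paste0(sn, "P")]] <- pvals
  }
  # previous-year predictors: value of the season in year y-1
  cur <- setdiff(names(out), "year")
  for (cl in cur)
    out[[paste0(cl, "t")]] <- out[[cl]][match(out$year - 1L, out$year)]
  out
}

#' Names of the 16 seasonal predictors
#' @return Character vector of predictor column names.
#' @export
seasonal_predictors <- function() {
  cur <- as.vector(outer(names(SEASONS), c("T", "P"), paste0))
  c(cur, paste0(cur, "t"))
}

#' Seasonal climate-chronology correlation screen
#'
#' Pearson correlation of an annual chronology with each of the 16 lagged
#' seasonal predictors, with pointwise two-sided 95% critical values from
#' the t distribution (n - 2 df) and a Bonferroni-adjusted p value across
#' the 16 predictors for honesty. The chronology (never the climate) can be
#' pre-smoothed with a 10-yr spline or 10-yr high-pass filtered.
#'
#' @param chron A `chronology` or data frame `year`, `value`.
#' @param seasonal Output of [seasonal_aggregate()].
#' @param window Optional year range.
#' @param smooth `"none"`, `"spline10"` or `"highpass10"`.
#' @param alpha Pointwise significance level (default 0.05).
#' @param min_years Minimum common years per predictor (default 10).
#' @return Data frame with one row per predictor: `predictor`, `season`,
#'   `variable`, `lag`, `n`, `r`, `crit`, `p`, `significant`, `p_bonf`.
#' @export
climate_correlation_screen <- function(chron, seasonal, window = NULL,
                                       smooth = c("none", "spline10",
                                                  "highpass10"),
                                       alpha = 0.05, min_years = 10) {
  smooth <- match.arg(smooth)
  d <- chron_values(chron)
  d <- d[window_years(d$year, window) & !is.na(d$value), , drop = FALSE]
  if (smooth == "spline10") {
    d$value <- spline_smooth(d$value, 10)
  } else if (smooth == "highpass10") {
    d$value <- highpass(d$value, 10)
    d <- d[!is.na(d$value), , drop = FALSE]
  }
  preds <- seasonal_predictors()
  rows <- lapply(preds, function(pn) {
    pv <- seasonal[[pn]][match(d$year, seasonal$year)]
    ok <- !is.na(pv) & !is.na(d$value)
    n <- sum(ok)
    if (n < min_years) {
      message("climate screen: skipping ", pn, " (", n, " common years)")
      return(NULL)
    }
    r <- stats::cor(d$value[ok], pv[ok])
    p <- cor_p_value(r, n)
    data.frame(predictor = pn,
               season = substr(pn, 1, 2),
               variable = substr(pn, 3, 3),
               lag = ifelse(substr(pn, 4, 4) == "t", "previous", "current"),
               n = n, r = r, crit = cor_critical(n, alpha), p = p,
               significant = abs(r) > cor_critical(n, alpha),
               p_bonf = min(1, p * length(preds)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) abort("climate screen: no predictor had enough years")
  rownames(out) <- NULL
  out
}
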