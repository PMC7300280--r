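# The d13C processing chain: discrimination, intercellular CO2, intrinsic
# water-use efficiency, and the atmospheric (Suess) correction.

#' Photosynthetic fractionation constants
#'
#' `a` is the fractionation from CO2 diffusion through the stomata
#' (~4.4 permil), `b` the fractionation during carboxylation (~27 permil).
#'
#' @param a Diffusion fractionation (permil).
#' @param b Carboxylation fractionation (permil); must exceed `a`.
#' @return A named list of class `frac_constants`.
#' @export
frac_constants <- function(a = 4.4, b = 27) {
  if (!(b > a)) abort("frac_constants: b must be > a")
  structure(list(a = a, b = b), class = "frac_constants")
}

#' Carbon isotope discrimination
#'
#' Delta = (d13Catm - d13Cplant) / (1 + d13Cplant/1000), the depletion of
#' 13C in plant matter relative to atmospheric CO2. Using the year-specific
#' atmospheric d13C makes Delta insensitive to the fossil-fuel depletion of
#' the atmosphere.
#'
#' @param d13c_plant Plant d13C (permil vs VPDB); must be > -1000.
#' @param d13c_atm Atmospheric d13C (permil).
#' @return Delta (permil), vectorised.
#' @export
discrimination <- function(d13c_plant, d13c_atm) {
  if (any(d13c_plant <= -1000)) abort("discrimination: d13c_plant must be > -1000")
  (d13c_atm - d13c_plant) / (1 + d13c_plant / 1000)
}

#' Intercellular CO2 from discrimination
#'
#' Inverts the linear model Delta = a + (b - a) * Ci/Ca:
#' Ci = Ca * (Delta - a) / (b - a). Values outside `[0, Ca]` (i.e. Delta
#' outside `[a, b]`) are returned but flagged in the `"out_of_range"`
#' attribute.
#'
#' @param delta Discrimination (permil).
#' @param ca Atmospheric CO2 concentration (umol/mol), > 0.
#' @param constants [frac_constants()].
#' @return Ci (umol/mol) with logical attribute `out_of_range`.
#' @export
ci_from_discrimination <- function(delta, ca, constants = frac_constants()) {
  if (any(ca <= 0)) abort("ci_from_discrimination: Ca must be > 0")
  ci <- ca * (delta - constants$a) / (constants$b - constants$a)
  attr(ci, "out_of_range") <- ci < 0 | ci > ca
  ci
}

#' Intrinsic water-use efficiency
#'
#' iWUE = (Ca - Ci) / 1.6, the ratio of CO2 assimilation to stomatal
#' conductance for water vapour (umol/mol); 1.6 is the ratio of the
#' diffusivities of water vapour and CO2 in air.
#'
#' @param ca Atmospheric CO2 (umol/mol), > 0.
#' @param ci Intercellular CO2 (umol/mol).
#' @return iWUE (umol/mol).
#' @export
iwue <- function(ca, ci) {
  if (any(ca <= 0)) abort("iwue: Ca must be > 0")
  (ca - ci) / 1.6
}

#' Suess correction of a d13C series
#'
#' Removes the fossil-fuel imprint from measured d13C for display and trend
#' work: corrected(t) = raw(t) - (d13Catm(t) - reference). Wherever the
#' atmosphere equals the reference the correction is zero. Note that the
#' discrimination/iWUE chain uses raw d13C with year-specific d13Catm and
#' needs no prior correction (double-correcting is a known pitfall).
#'
#' @param values Measured d13C (permil).
#' @param years Calendar years matching `values`.
#' @param atm Atmospheric record (`year`, `d13c_atm`).
#' @param reference Reference (pre-industrial) atmospheric d13C, permil.
#' @return Corrected d13C values.
#' @export
suess_correct <- function(values, years, atm, reference = -6.4) {
  idx <- match(years, atm$year)
  if (anyNA(idx))
    abort("suess_correct: year(s) outside atmospheric record: ",
          paste(utils::head(years[is.na(idx)], 5), collapse = ", "))
  values - (atm$d13c_atm[idx] - reference)
}

#' Full isotope chain for one tree
#'
#' From raw d13C and the year-matched atmosphere: Suess-corrected d13C,
#' discrimination, intercellular CO2 and iWUE.
#'
#' @param d13c Data frame `year`, `d13c` for one tree.
#' @param atm Atmospheric record (`year`, `ca`, `d13c_atm`).
#' @param constants [frac_constants()].
#' @param reference Suess-correction reference (permil).
#' @return Data frame `year`, `d13c_raw`, `d13c_corrected`, `delta`, `ci`,
#'   `iwue`, `ci_out_of_range`.
#' @export
iwue_series <- function(d13c, atm, constants = frac_constants(),
                        reference = -6.4) {
  idx <- match(d13c$year, atm$year)
  if (anyNA(idx))
    abort("iwue_series: year(s) outside atmospheric record: ",
          paste(utils::head(d13c$year[is.na(idx)], 5), collapse = ", "))
  delta <- discrimination(d13c$d13c, atm$d13c_atm[idx])
  ci <- ci_from_discrimination(delta, atm$ca[idx], constants)
  data.frame(
    year = d13c$year,
    d13c_raw = d13c$d13c,
    d13c_corrected = suess_correct(d13c$d13c, d13c$year, atm, reference),
    delta = delta,
    ci = as.numeric(ci),
    iwue = iwue(atm$ca[idx], as.numeric(ci)),
    ci_out_of_range = attr(ci, "out_of_range"))
}

#' Group iWUE chronology with subperiod statistics
#'
#' Applies the isotope chain per tree, averages trees into annual group
#' chronologies of d13C and iWUE, and computes, per analysis window, the
#' mean interseries correlation, chronology mean +/- SD and OLS slope for
#' both variables.
#'
#' @param isotopes Long data frame `tree_id`, `year`, `d13c` (one group).
#' @param atm Atmospheric record.
#' @param constants [frac_constants()].
#' @param windows Named list of year ranges, e.g.
#'   `list(period1 = c(1880, 1915), period2 = c(1980, 2015))`.
#' @param group Group label.
#' @param reference Suess-correction reference (permil).
#' @return List with `per_tree` (long data frame of the full chain),
#'   `chron_iwue`, `chron_d13c` (class `chronology`) and `stats`
#'   (one row per window x variable).
#' @export
iwue_chronology <- function(isotopes, atm, constants = frac_constants(),
                            windows = NULL, group = NA_character_,
                            reference = -6.4) {
  if (!nrow(isotopes)) abort("iwue_chronology: no isotope data")
  per_tree <- do.call(rbind, lapply(split(isotopes, isotopes$tree_id),
    function(d) {
      out <- iwue_series(d[, c("year", "d13c")], atm, constants, reference)
      cbind(tree_id = d$tree_id[1], out, stringsAsFactors = FALSE)
    }))
  rownames(per_tree) <- NULL
  iw <- per_tree[, c("tree_id", "year", "iwue")]
  dc <- per_tree[, c("tree_id", "year", "d13c_raw")]
  chron_iwue <- build_chronology(iw, "iWUE", group = group, value = "iwue")
  chron_d13c <- build_chronology(dc, "d13C", group = group,
                                 value = "d13c_raw")
  stats_rows <- list()
  for (wn in names(windows %||% list())) {
    w <- windows[[wn]]
    for (v in c("iWUE", "d13C")) {
      ch <- if (v == "iWUE") chron_iwue else chron_d13c
      memb <- if (v == "iWUE") iw else dc
      sel <- window_years(ch$series$year, w)
      vals <- ch$series$mean[sel]
      rbar_w <- tryCatch(mean_interseries_r(memb, window = w),
                         error = function(e) NA_real_)
      tr <- tryCatch(linear_trend(ch, window = w),
                     error = function(e) list(slope = NA_real_, p = NA_real_,
                                              significant = NA))
      stats_rows[[paste(wn, v)]] <- data.frame(
        group = group, window = wn, variable = v,
        first = min(w), last = max(w),
        n_trees = length(unique(memb$tree_id)),
        r = rbar_w, mean = mean(vals), sd = stats::sd(vals),
        slope = tr$slope, slope_p = tr$p,
        slope_significant = tr$significant, stringsAsFactors = FALSE)
    }
  }
  stats <- if (length(stats_rows)) do.call(rbind, stats_rows) else NULL
  if (!is.null(stats)) rownames(stats) <- NULL
  list(per_tree = per_tree, chron_iwue = chron_iwue,
       chron_d13c = chron_d13c, stats = stats)
}
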