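# Synthetic-forest generator: a complete dataset (climate, atmosphere,
# isotopes, ring widths, metadata) with the statistical structure the
# analysis assumes and full ground truth, used by tests and by the
# end-to-end pipeline demo.

#' Define a synthetic forest scenario
#'
#' Bundles every knob of the generator: three genetic groups of oaks
#' sampled over 1860-2015, a Mediterranean-mountain monthly climatology
#' warming ~1.3 degC per century and drying ~100 mm per century, a smooth
#' monotone CO2 path rising from ~290 ppm to ~400 ppm with the matching
#' fossil-fuel depletion of atmospheric d13C, per-group baseline d13C with
#' a summer-temperature sensitivity, and gamma-distributed BAI driven by
#' standardised seasonal climate and iWUE with per-tree random intercepts
#' and iWUE slopes. Scenario coefficients are expressed on z-score
#' predictor scales relative to `std_window`, so they are directly
#' comparable to fitted standardized coefficients.
#'
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the scenario including this seed.
#' @param years Calendar span of the simulation.
#' @param groups Group labels.
#' @param trees_per_group Trees sampled per group.
#' @param isotope_trees_per_group Trees per group with d13C series.
#' @param window1,window2 The two contrasting analysis windows.
#' @param climate,atmosphere,isotope,growth Named lists overriding the
#'   default parameter blocks (partial overrides allowed).
#' @return Object of class `forest_scenario`.
#' @export
forest_scenario <- function(seed = 1,
                            years = 1860:2015,
                            groups = c("QuPe", "QuHy", "QuPy"),
                            trees_per_group = 20,
                            isotope_trees_per_group = 5,
                            window1 = c(1880, 1915),
                            window2 = c(1980, 2015),
                            climate = list(),
                            atmosphere = list(),
                            isotope = list(),
                            growth = list()) {
  cl <- utils::modifyList(list(
    tmean_annual = 5.7,        # window-1 mean annual temperature (degC)
    tmean_amplitude = 7.5,     # seasonal half-range (degC)
    warming_per_year = 0.013,  # +1.3 degC per century
    precip_annual = 1200,      # window-1 annual precipitation (mm)
    precip_summer_dry = 0.55,  # summer-dry modulation of monthly totals
    precip_trend_per_year = -1.0,  # mm of annual total lost per year
    ar1 = 0.3,                 # interannual AR(1) of the shared year effect
    tmean_year_sd = 0.3,       # SD of the shared annual T anomaly (degC)
    tmean_month_sd = 0.9,      # independent monthly T noise (degC)
    precip_year_sd = 0.10,     # relative SD of the shared annual P anomaly
    precip_month_sd = 0.25,    # independent relative monthly P noise
    long_t_offset = 5.8,       # long (lowland) record is warmer by this
    long_p_ratio = 0.45,       # and drier by this factor
    target_span = c(1946, 2015),
    long_span = c(1860, 2005)), climate)
  at <- utils::modifyList(list(
    ca_start = 288, ca_end = 400.5,    # ppm at span endpoints
    rate = 0.032, midpoint = 1990,     # logistic shape of the CO2 path
    reference_d13c = -6.4,             # pre-industrial atmospheric d13C
    modern_d13c = -8.4,                # value reached at ca_end
    suess = TRUE), atmosphere)
  iso <- utils::modifyList(list(
    d13c_base = c(QuPe = -18.6, QuHy = -19.4, QuPy = -19.6),
    summer_t_sens = 0.25,      # permil of d13C per degC of summer T
    resid_sd = 0.25), isotope) # per-tree-year residual SD (permil)
  gr <- utils::modifyList(list(
    log_bai_mean = 7.75,       # exp(.) ~ 2320 mm^2/yr
    beta = c(iwue = 0.030, SuP = 0.116, SpP = -0.046, WiT = -0.114,
             SuTt = -0.059),
    beta_size = 0,             # effect of the latent per-tree size factor
    sd_intercept = 0.20,
    sd_iwue_slope = 0.06,
    shape = 15,                # gamma shape (interannual CV ~ 0.26)
    std_window = "window1"), growth)
  stopifnot(cl$tmean_amplitude >= 0, cl$precip_annual > 0,
            gr$sd_intercept >= 0, gr$sd_iwue_slope >= 0, gr$shape > 0,
            iso$resid_sd >= 0, at$ca_start > 0, at$ca_end > at$ca_start)
  if (!all(names(iso$d13c_base) %in% groups) && length(groups) ==
      length(iso$d13c_base))
    names(iso$d13c_base) <- groups
  structure(list(seed = as.integer(seed), years = years, groups = groups,
                 trees_per_group = trees_per_group,
                 isotope_trees_per_group = isotope_trees_per_group,
                 window1 = window1, window2 = window2,
                 climate = cl, atmosphere = at, isotope = iso, growth = gr),
            class = "forest_scenario")
}

#' Table-5-like period-2 scenario
#'
#' Same generator with the second window as the focal period: no iWUE
#' effect, a positive tree-size effect, and lagged-climate drivers with
#' the printed coefficient magnitudes as planted truths (scenario
#' parameters, not reproduction claims).
#'
#' @param seed Integer seed.
#' @param ... Further overrides passed to [forest_scenario()].
#' @return A `forest_scenario`.
#' @export
scenario_period2 <- function(seed = 1, ...) {
  forest_scenario(seed = seed,
                  growth = list(beta = c(SpT = -0.036, WiT = -0.046,
                                         WiP = -0.018, SuTt = 0.039,
                                         SuPt = 0.096, SpPt = -0.040,
                                         WiTt = -0.016),
                                beta_size = 0.022, sd_iwue_slope = 0,
                                std_window = "window2"),
                  ...)
}

#' Generate monthly climate records
#'
#' Sinusoidal monthly climatology plus linear warming/drying trends and a
#' two-layer anomaly structure: a weak AR(1) year effect shared by all
#' months of a year (giving the modest cross-season correlation of real
#' records) and dominant independent monthly noise. Returns the full
#' "true" record, the short local
#' (`target`) record, and a long distant (`long`) record that is the exact
#' constant-offset / constant-ratio transform of the truth, so
#' [rescale_long_record()] can recover the truth on the overlap.
#'
#' @param scenario A `forest_scenario`. Uses the current RNG stream.
#' @return List of monthly data frames `true`, `target`, `long`.
#' @export
generate_climate <- function(scenario) {
  cl <- scenario$climate
  yrs <- (min(scenario$years) - 1L):max(scenario$years)  # extra Dec for DJF
  ny <- length(yrs)
  center <- mean(scenario$window1)  # climatology anchored to window 1
  ar_t <- as.numeric(stats::filter(stats::rnorm(ny,
    sd = cl$tmean_year_sd * sqrt(1 - cl$ar1^2)), cl$ar1,
    method = "recursive"))
  ar_p <- as.numeric(stats::filter(stats::rnorm(ny,
    sd = cl$precip_year_sd * sqrt(1 - cl$ar1^2)), cl$ar1,
    method = "recursive"))
  rows <- vector("list", ny)
  for (i in seq_len(ny)) {
    y <- yrs[i]
    m <- 1:12
    t_clim <- cl$tmean_annual + cl$tmean_amplitude * cos(2 * pi * (m - 7) / 12)
    p_clim <- cl$precip_annual / 12 *
      (1 - cl$precip_summer_dry * cos(2 * pi * (m - 7) / 12))
    tmean <- t_clim + cl$warming_per_year * (y - center) + ar_t[i] +
      stats::rnorm(12, sd = cl$tmean_month_sd)
    p_fac <- 1 + cl$precip_trend_per_year * (y - center) / cl$precip_annual
    psum <- pmax(0, p_clim * p_fac *
                   (1 + ar_p[i] + stats::rnorm(12, sd = cl$precip_month_sd)))
    rows[[i]] <- data.frame(year = y, month = m, tmean = tmean, psum = psum)
  }
  true <- do.call(rbind, rows)
  target <- true[true$year >= cl$target_span[1] &
                   true$year <= cl$target_span[2], ]
  long <- true[true$year >= cl$long_span[1] & true$year <= cl$long_span[2], ]
  long$tmean <- long$tmean + cl$long_t_offset
  long$psum <- long$psum * cl$long_p_ratio
  rownames(true) <- rownames(target) <- rownames(long) <- NULL
  list(true = true, target = target, long = long)
}

#' Generate the atmospheric CO2 / d13C history
#'
#' A monotone logistic-shaped Ca path passing exactly through the
#' configured endpoints, and an atmospheric d13C declining linearly in Ca
#' from the pre-industrial reference to the modern value (constant at the
#' reference when the Suess imprint is switched off). Deterministic.
#'
#' @param scenario A `forest_scenario`.
#' @return Data frame `year`, `ca`, `d13c_atm`.
#' @export
generate_atmosphere <- function(scenario) {
  at <- scenario$atmosphere
  yrs <- scenario$years
  g <- 1 / (1 + exp(-at$rate * (yrs - at$midpoint)))
  g0 <- g[1]; g1 <- g[length(g)]
  ca <- at$ca_start + (at$ca_end - at$ca_start) * (g - g0) / (g1 - g0)
  d13c_atm <- if (isTRUE(at$suess)) {
    at$reference_d13c + (at$modern_d13c - at$reference_d13c) *
      (ca - at$ca_start) / (at$ca_end - at$ca_start)
  } else rep(at$reference_d13c, length(yrs))
  data.frame(year = yrs, ca = ca, d13c_atm = d13c_atm)
}

#' Generate per-tree isotope series and the iWUE ground truth
#'
#' Physiology is defined in discrimination space: each group has a baseline
#' d13C (referred to the pre-industrial atmosphere), shifted by a
#' summer-temperature sensitivity and tree-year noise; the implied
#' discrimination is mapped through the year's real atmosphere to the
#' measured d13C, and through Ci to the true iWUE. Applying the package's
#' isotope chain to the generated d13C recovers the truth exactly (up to
#' float error).
#'
#' @param scenario A `forest_scenario`. Uses the current RNG stream.
#' @param seasonal Seasonal predictors of the true climate
#'   ([seasonal_aggregate()]).
#' @param atm Atmospheric record ([generate_atmosphere()]).
#' @param constants [frac_constants()].
#' @return List with `d13c` (long `tree_id`, `group`, `year`, `d13c`),
#'   `truth` (per tree-year `delta`, `ci`, `iwue`) and `truth_group`
#'   (`group`, `year`, `iwue` mean over isotope trees).
#' @export
generate_isotopes <- function(scenario, seasonal, atm,
                              constants = frac_constants()) {
  iso <- scenario$isotope
  at <- scenario$atmosphere
  yrs <- scenario$years
  sut <- seasonal$SuT[match(yrs, seasonal$year)]
  sut_anom <- sut - mean(sut)
  d13c_rows <- truth_rows <- list()
  for (gr in scenario$groups) {
    base <- iso$d13c_base[[gr]]
    for (ti in seq_len(scenario$isotope_trees_per_group)) {
      id <- sprintf("%s_%02d", gr, ti)
      shift <- iso$summer_t_sens * sut_anom +
        stats::rnorm(length(yrs), sd = iso$resid_sd)
      d13c_phys <- base + shift   # physiological d13C at reference atmosphere
      delta <- (at$reference_d13c - d13c_phys) / (1 + d13c_phys / 1000)
      d13c_meas <- (atm$d13c_atm - delta) / (1 + delta / 1000)
      ci <- atm$ca * (delta - constants$a) / (constants$b - constants$a)
      true_iwue <- (atm$ca - ci) / 1.6
      d13c_rows[[id]] <- data.frame(tree_id = id, group = gr, year = yrs,
                                    d13c = d13c_meas,
                                    stringsAsFactors = FALSE)
      truth_rows[[id]] <- data.frame(tree_id = id, group = gr, year = yrs,
                                     delta = delta, ci = ci,
                                     iwue = true_iwue,
                                     stringsAsFactors = FALSE)
    }
  }
  d13c <- do.call(rbind, d13c_rows)
  truth <- do.call(rbind, truth_rows)
  rownames(d13c) <- rownames(truth) <- NULL
  gm <- stats::aggregate(iwue ~ group + year, truth, mean)
  list(d13c = d13c, truth = truth,
       truth_group = gm[order(gm$group, gm$year), ])
}

# z-scores of a year-level series relative to the scenario's std_window
scenario_zscore <- function(values, years, scenario) {
  w <- scenario[[scenario$growth$std_window]]
  sel <- window_years(years, w)
  (values - mean(values[sel])) / stats::sd(values[sel])
}

#' Generate ring-width series, metadata and the BAI ground truth
#'
#' Per tree i and year t, BAI ~ Gamma(shape, mean = exp(eta_it)) with
#' eta_it = beta0 + sum_s beta_s z_st + (beta_w + b_i) z_iwue(g,t)
#' + beta_size s_i + u_i, where z are z-scores of the seasonal predictors
#' and the group iWUE chronology relative to the scenario's standardisation
#' window, u_i and b_i are Gaussian per-tree effects and s_i a latent
#' standard-normal size factor. Ring widths invert the cumulative disc-area
#' relation, DBH is twice the final radius, so [bai_from_widths()] on the
#' generated widths returns the generated BAI exactly.
#'
#' @param scenario A `forest_scenario`. Uses the current RNG stream.
#' @param seasonal Seasonal predictors of the true climate.
#' @param iwue_truth_group `truth_group` from [generate_isotopes()].
#' @return List with `rings` (list of [ring_series()]), `meta`, `bai`
#'   (long truth), `effects` (per-tree `u`, `b`, `size`).
#' @export
generate_trees_and_growth <- function(scenario, seasonal, iwue_truth_group) {
  gr <- scenario$growth
  yrs <- scenario$years
  beta <- gr$beta
  clim_names <- setdiff(names(beta), "iwue")
  Z <- sapply(clim_names, function(pn)
    scenario_zscore(seasonal[[pn]][match(yrs, seasonal$year)], yrs, scenario))
  Z <- matrix(Z, nrow = length(yrs),
              dimnames = list(NULL, clim_names))
  z_iwue <- lapply(stats::setNames(scenario$groups, scenario$groups),
    function(g) {
      gi <- iwue_truth_group[iwue_truth_group$group == g, ]
      scenario_zscore(gi$iwue[match(yrs, gi$year)], yrs, scenario)
    })
  beta_w <- if ("iwue" %in% names(beta)) beta[["iwue"]] else 0
  rings <- list(); meta_rows <- list(); bai_rows <- list(); eff_rows <- list()
  for (g in scenario$groups) {
    for (ti in seq_len(scenario$trees_per_group)) {
      id <- sprintf("%s_%02d", g, ti)
      u <- stats::rnorm(1, sd = gr$sd_intercept)
      b <- stats::rnorm(1, sd = gr$sd_iwue_slope)
      s <- stats::rnorm(1)
      eta <- gr$log_bai_mean + as.numeric(Z %*% beta[clim_names]) +
        (beta_w + b) * z_iwue[[g]] + gr$beta_size * s + u
      mu <- exp(eta)
      bai <- stats::rgamma(length(yrs), shape = gr$shape,
                           rate = gr$shape / mu)
      r <- sqrt(cumsum(bai) / pi)
      widths <- diff(c(0, r))
      rings[[id]] <- ring_series(id, min(yrs), widths, group = g)
      meta_rows[[id]] <- data.frame(
        tree_id = id, group = g,
        dbh = 2 * r[length(r)] / 10,                       # mm -> cm
        height = round(14 + 2.5 * s + stats::rnorm(1), 1),
        stringsAsFactors = FALSE)
      bai_rows[[id]] <- data.frame(tree_id = id, group = g, year = yrs,
                                   bai = bai, stringsAsFactors = FALSE)
      eff_rows[[id]] <- data.frame(tree_id = id, group = g, u = u, b = b,
                                   size = s, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta_rows)
  meta$height <- pmax(meta$height, 5)
  bai <- do.call(rbind, bai_rows)
  effects <- do.call(rbind, eff_rows)
  rownames(meta) <- rownames(bai) <- rownames(effects) <- NULL
  list(rings = rings, meta = meta, bai = bai, effects = effects)
}

#' Generate a complete synthetic forest dataset
#'
#' Runs the whole generative chain (climate, atmosphere, isotopes, growth)
#' under the scenario's seed. Identical scenarios produce bit-identical
#' outputs.
#'
#' @param scenario A `forest_scenario`.
#' @return List with `scenario`, `climate` (`true`, `target`, `long`),
#'   `seasonal` (of the true record), `atmosphere`, `isotopes` (see
#'   [generate_isotopes()]), `trees` (see [generate_trees_and_growth()])
#'   and `truth` (planted parameter values).
#' @export
generate_forest <- function(scenario = forest_scenario()) {
  with_seed(scenario$seed, {
    climate <- generate_climate(scenario)
    seasonal <- seasonal_aggregate(climate$true)
    atm <- generate_atmosphere(scenario)
    isotopes <- generate_isotopes(scenario, seasonal, atm)
    trees <- generate_trees_and_growth(scenario, seasonal,
                                       isotopes$truth_group)
    list(scenario = scenario, climate = climate, seasonal = seasonal,
         atmosphere = atm, isotopes = isotopes, trees = trees,
         truth = list(beta = scenario$growth$beta,
                      beta_size = scenario$growth$beta_size,
                      log_bai_mean = scenario$growth$log_bai_mean,
                      sd_intercept = scenario$growth$sd_intercept,
                      sd_iwue_slope = scenario$growth$sd_iwue_slope,
                      shape = scenario$growth$shape))
  })
}

#' Write a generated forest to disk in the pipeline's input formats
#'
#' Emits `cores.rwl` (0.001 mm dialect), `trees.csv`, `d13c.csv`,
#' `atm.csv`, `climate_target.csv`, `climate_long.csv` and `truth.json`.
#'
#' @param forest Output of [generate_forest()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_forest <- function(forest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_rwl(forest$trees$rings, file.path(dir, "cores.rwl"))
  utils::write.csv(forest$trees$meta, file.path(dir, "trees.csv"),
                   row.names = FALSE)
  utils::write.csv(forest$isotopes$d13c[, c("tree_id", "year", "d13c")],
                   file.path(dir, "d13c.csv"), row.names = FALSE)
  utils::write.csv(forest$atmosphere, file.path(dir, "atm.csv"),
                   row.names = FALSE)
  utils::write.csv(forest$climate$target,
                   file.path(dir, "climate_target.csv"), row.names = FALSE)
  utils::write.csv(forest$climate$long,
                   file.path(dir, "climate_long.csv"), row.names = FALSE)
  truth <- forest$truth
  truth$beta <- as.list(truth$beta)  # keep names in the JSON object
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
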