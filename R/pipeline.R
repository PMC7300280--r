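# End-to-end orchestration: simulate -> chronologies -> iWUE -> climate
# screens -> group comparisons -> growth GLMM, with a config object, stage
# logging and a deterministic run manifest.

#' Build a pipeline run configuration
#'
#' @param outdir Output directory for all stage outputs.
#' @param scenario `"period1"`, `"period2"`, a [forest_scenario()], or
#'   `NULL` to analyse pre-existing input files.
#' @param inputs Named list of input file paths (`rwl`, `meta`, `d13c`,
#'   `atm`, `climate_target`, `climate_long`); filled automatically when a
#'   scenario is simulated.
#' @param seed Integer seed governing every stochastic stage.
#' @param windows Named list of the two analysis windows.
#' @param constants Isotope constants (`a`, `b`, `suess_reference`).
#' @param smooth_bai Chronology smoothing for the BAI climate screen
#'   (`"spline10"`, `"highpass10"` or `"none"`).
#' @param glmm List with `candidates` (fixed-effect candidates), `random`
#'   (random structures to compare), `max_fixed`, `delta`, `window`
#'   (`"window1"` or `"window2"`), `vif_threshold`.
#' @return List of class `run_config`.
#' @export
run_config <- function(outdir,
                       scenario = "period1",
                       inputs = NULL,
                       seed = 1,
                       windows = list(window1 = c(1880, 1915),
                                      window2 = c(1980, 2015)),
                       constants = list(a = 4.4, b = 27,
                                        suess_reference = -6.4),
                       smooth_bai = "spline10",
                       glmm = list()) {
  glmm <- utils::modifyList(list(
    candidates = c("iwue", "dbh", "SuP", "SpT", "SpP", "WiT", "SuTt",
                   "SpPt"),
    random = c("none", "intercept", "intercept+iwue"),
    max_fixed = 6, delta = 6, window = "window1", vif_threshold = 2,
    nsim_band = 200), glmm)
  w1 <- unlist(windows[[1]]); w2 <- unlist(windows[[2]])
  if (max(w1) >= min(w2) && max(w2) >= min(w1))
    abort("run_config: analysis windows must not overlap")
  structure(list(outdir = outdir, scenario = scenario, inputs = inputs,
                 seed = as.integer(seed), windows = windows,
                 constants = constants, smooth_bai = smooth_bai,
                 glmm = glmm),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$outdir)) abort("config: 'outdir' is required")
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

stage_log <- function(name, t0, ...) {
  message(sprintf("[ringflux] stage %-9s %6.2fs  %s", name,
                  as.numeric(Sys.time()) - t0, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when a scenario is configured), chron, iwue,
#' climcorr, groups and glmm in order; each stage reads only declared
#' files, writes CSV/JSON outputs into `outdir`, and any failure aborts
#' with the stage name. A manifest (config echo, seed, package version,
#' per-stage outputs with row counts and content hashes) is written as
#' `manifest.json`; reruns with the same config and seed are bit-identical.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "ringflux",
                   version = as.character(utils::packageVersion("ringflux")),
                   seed = config$seed,
                   config = config_echo(config),
                   stages = list())
  run_stage <- function(name, fun) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(fun(), error = function(e)
      abort("stage ", name, " failed: ", conditionMessage(e)))
    files <- res$files
    rows <- vapply(files, function(f) {
      if (grepl("\\.csv$", f))
        nrow(utils::read.csv(file.path(outdir, f))) else NA_integer_
    }, integer(1))
    manifest$stages[[name]] <<- list(outputs = as.list(files),
                                     rows = as.list(rows))
    stage_log(name, t0, length(files), " file(s)")
    res
  }
  w1 <- unlist(config$windows[[1]]); w2 <- unlist(config$windows[[2]])
  constants <- frac_constants(config$constants$a, config$constants$b)
  ref <- config$constants$suess_reference
  paths <- config$inputs

  # -- simulate ------------------------------------------------------------
  if (!is.null(config$scenario)) {
    run_stage("simulate", function() {
      sc <- config$scenario
      if (is.character(sc)) {
        sc <- switch(sc,
                     period1 = forest_scenario(seed = config$seed),
                     period2 = scenario_period2(seed = config$seed),
                     abort("unknown scenario '", sc, "'"))
      }
      forest <- generate_forest(sc)
      ddir <- file.path(outdir, "data")
      write_forest(forest, ddir)
      paths <<- list(rwl = file.path(ddir, "cores.rwl"),
                     meta = file.path(ddir, "trees.csv"),
                     d13c = file.path(ddir, "d13c.csv"),
                     atm = file.path(ddir, "atm.csv"),
                     climate_target = file.path(ddir, "climate_target.csv"),
                     climate_long = file.path(ddir, "climate_long.csv"))
      list(files = file.path("data", c("cores.rwl", "trees.csv", "d13c.csv",
                                       "atm.csv", "climate_target.csv",
                                       "climate_long.csv", "truth.json")))
    })
  }
  if (is.null(paths)) abort("run_pipeline: no inputs and no scenario")

  # -- chronologies --------------------------------------------------------
  run_stage("chron", function() {
    rings <- read_rwl(paths$rwl)
    meta <- read_tree_meta(paths$meta)
    validate_dataset(rings, meta)
    bai <- bai_all(rings, meta)
    utils::write.csv(bai, file.path(outdir, "bai.csv"), row.names = FALSE)
    chron_rows <- list(); stat_rows <- list(); chrons <- list()
    for (g in sort(unique(meta$group))) {
      memb <- bai[bai$group == g, c("tree_id", "year", "bai")]
      ch <- build_chronology(memb, "BAI", group = g)
      chrons[[g]] <- ch
      chron_rows[[g]] <- cbind(group = g, ch$series,
                               stringsAsFactors = FALSE)
      for (wn in names(config$windows)) {
        w <- unlist(config$windows[[wn]])
        rbar_w <- tryCatch(mean_interseries_r(memb, window = w),
                           error = function(e) NA_real_)
        sel <- window_years(ch$series$year, w)
        tr <- tryCatch(linear_trend(ch, window = w), error = function(e)
          list(slope = NA_real_, p = NA_real_, significant = NA))
        stat_rows[[paste(g, wn)]] <- data.frame(
          group = g, window = wn, first = min(w), last = max(w),
          n_trees = ch$n_trees,
          span_first = min(ch$series$year), span_last = max(ch$series$year),
          reliable_first = ch$reliable_span[1],
          reliable_last = ch$reliable_span[2],
          r = rbar_w,
          eps = if (!is.na(rbar_w)) suppressWarnings(eps(rbar_w, ch$n_trees))
                else NA_real_,
          mean = mean(ch$series$mean[sel]), sd = stats::sd(ch$series$mean[sel]),
          slope = tr$slope, slope_p = tr$p, slope_significant = tr$significant,
          stringsAsFactors = FALSE)
      }
    }
    utils::write.csv(do.call(rbind, chron_rows),
                     file.path(outdir, "chron.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, stat_rows),
                     file.path(outdir, "chron_stats.csv"), row.names = FALSE)
    corr_rows <- list()
    gs <- names(chrons)
    for (wn in names(config$windows)) {
      w <- unlist(config$windows[[wn]])
      for (i in seq_along(gs)) for (j in seq_along(gs)) {
        if (i >= j) next
        raw <- chronology_correlation(chrons[[gs[i]]], chrons[[gs[j]]],
                                      window = w, filtered = FALSE)
        hp <- chronology_correlation(chrons[[gs[i]]], chrons[[gs[j]]],
                                     window = w, filtered = TRUE)
        corr_rows[[paste(wn, i, j)]] <- data.frame(
          window = wn, group_a = gs[i], group_b = gs[j],
          r = raw$r, p = raw$p, sig99 = raw$sig99,
          r_highpass = hp$r, p_highpass = hp$p, sig99_highpass = hp$sig99,
          stringsAsFactors = FALSE)
      }
    }
    utils::write.csv(do.call(rbind, corr_rows),
                     file.path(outdir, "chron_corr.csv"), row.names = FALSE)
    list(files = c("bai.csv", "chron.csv", "chron_stats.csv",
                   "chron_corr.csv"))
  })

  # -- isotopes / iWUE -----------------------------------------------------
  run_stage("iwue", function() {
    meta <- read_tree_meta(paths$meta)
    isotopes <- read_isotope_series(paths$d13c, meta)
    atm <- read_atmosphere(paths$atm)
    validate_dataset(read_rwl(paths$rwl), meta, isotopes, atm,
                     windows = config$windows)
    per_tree <- list(); chron_rows <- list(); stat_rows <- list()
    for (g in sort(unique(isotopes$group))) {
      res <- iwue_chronology(isotopes[isotopes$group == g, ], atm,
                             constants,
                             windows = lapply(config$windows, unlist),
                             group = g, reference = ref)
      per_tree[[g]] <- cbind(group = g, res$per_tree,
                             stringsAsFactors = FALSE)
      chron_rows[[g]] <- data.frame(
        group = g, year = res$chron_iwue$series$year,
        iwue = res$chron_iwue$series$mean,
        d13c = res$chron_d13c$series$mean[
          match(res$chron_iwue$series$year, res$chron_d13c$series$year)],
        depth = res$chron_iwue$series$depth, stringsAsFactors = FALSE)
      stat_rows[[g]] <- res$stats
    }
    utils::write.csv(do.call(rbind, per_tree),
                     file.path(outdir, "iwue.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, chron_rows),
                     file.path(outdir, "iwue_chron.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, stat_rows),
                     file.path(outdir, "iwue_stats.csv"), row.names = FALSE)
    list(files = c("iwue.csv", "iwue_chron.csv", "iwue_stats.csv"))
  })

  # -- climate screens -----------------------------------------------------
  run_stage("climcorr", function() {
    target <- read_monthly_climate(paths$climate_target)
    long <- read_monthly_climate(paths$climate_long)
    merged <- rescale_long_record(long, target)
    utils::write.csv(merged, file.path(outdir, "climate_merged.csv"),
                     row.names = FALSE)
    seasonal <- seasonal_aggregate(merged)
    utils::write.csv(seasonal, file.path(outdir, "seasonal.csv"),
                     row.names = FALSE)
    chron <- utils::read.csv(file.path(outdir, "chron.csv"))
    iw <- utils::read.csv(file.path(outdir, "iwue_chron.csv"))
    rows <- list()
    for (g in sort(unique(chron$group))) {
      for (wn in names(config$windows)) {
        w <- unlist(config$windows[[wn]])
        cb <- data.frame(year = chron$year[chron$group == g],
                         value = chron$mean[chron$group == g])
        scr <- climate_correlation_screen(cb, seasonal, window = w,
                                          smooth = config$smooth_bai)
        rows[[paste(g, wn, "BAI")]] <- cbind(group = g, window = wn,
                                             response = "BAI", scr,
                                             stringsAsFactors = FALSE)
        cd <- data.frame(year = iw$year[iw$group == g],
                         value = iw$d13c[iw$group == g])
        scr <- climate_correlation_screen(cd, seasonal, window = w,
                                          smooth = "none")
        rows[[paste(g, wn, "d13C")]] <- cbind(group = g, window = wn,
                                              response = "d13C", scr,
                                              stringsAsFactors = FALSE)
      }
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(outdir, "climcorr.csv"), row.names = FALSE)
    list(files = c("climate_merged.csv", "seasonal.csv", "climcorr.csv"))
  })

  # -- group comparisons ---------------------------------------------------
  run_stage("groups", function() {
    bai <- utils::read.csv(file.path(outdir, "bai.csv"))
    iw <- utils::read.csv(file.path(outdir, "iwue.csv"))
    iw_long <- data.frame(tree_id = iw$tree_id, group = iw$group,
                          year = iw$year, iwue = iw$iwue)
    res <- list(BAI = period_difference(bai, w1, w2, value = "bai"),
                iWUE = period_difference(iw_long, w1, w2, value = "iwue"))
    trees <- do.call(rbind, lapply(names(res), function(v)
      cbind(variable = v, res[[v]]$trees, stringsAsFactors = FALSE)))
    within <- do.call(rbind, lapply(names(res), function(v)
      cbind(variable = v, res[[v]]$within, stringsAsFactors = FALSE)))
    between <- do.call(rbind, lapply(names(res), function(v) {
      cg <- res[[v]]$between
      pm <- cg$nemenyi$p_matrix
      pairs <- utils::combn(rownames(pm), 2)
      data.frame(variable = v, H = cg$kruskal$statistic,
                 p = cg$kruskal$p_value,
                 pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
                 pair_p = pm[t(pairs)],
                 letters = paste(names(cg$nemenyi$letters),
                                 cg$nemenyi$letters, sep = "=",
                                 collapse = " "),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(trees, file.path(outdir, "groups_trees.csv"),
                     row.names = FALSE)
    utils::write.csv(within, file.path(outdir, "groups_within.csv"),
                     row.names = FALSE)
    utils::write.csv(between, file.path(outdir, "groups_between.csv"),
                     row.names = FALSE)
    list(files = c("groups_trees.csv", "groups_within.csv",
                   "groups_between.csv"))
  })

  # -- growth model --------------------------------------------------------
  run_stage("glmm", function() {
    bai <- utils::read.csv(file.path(outdir, "bai.csv"))
    meta <- read_tree_meta(paths$meta)
    seasonal <- utils::read.csv(file.path(outdir, "seasonal.csv"))
    iwg <- utils::read.csv(file.path(outdir, "iwue_chron.csv"))
    w <- unlist(config$windows[[config$glmm$window]])
    md <- build_model_data(bai, meta, seasonal,
                           iwg[, c("group", "year", "iwue")], w)
    cand <- intersect(config$glmm$candidates, names(md))
    vf <- vif_filter(md[cand], threshold = config$glmm$vif_threshold)
    # stage 1: fixed-effect subsets under the marginal (random-free) model
    enum <- enumerate_and_select(md, vf$retained,
                                 random_structures = "none",
                                 max_fixed = config$glmm$max_fixed,
                                 delta = config$glmm$delta)
    best_fixed <- enum$best$fixed
    # stage 2: random structures on the winning fixed set
    fits <- list()
    for (rs in config$glmm$random) {
      slope <- setdiff(parse_random(rs), "intercept")
      if (length(slope) && !slope %in% best_fixed) next
      fits[[rs]] <- tryCatch(fit_growth_model(md, best_fixed, rs),
                             error = function(e) NULL)
    }
    fits <- Filter(Negate(is.null), fits)
    aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
    amin <- min(aiccs)
    elig <- names(fits)[aiccs <= amin + config$glmm$delta]
    ks <- vapply(fits[elig], function(f) f$k, numeric(1))
    best <- fits[[elig[order(ks, aiccs[elig])][1]]]
    lrt_rows <- list()
    if (!identical(best$random, "none")) {
      reds <- if (identical(best$random, "intercept")) "none"
      else c("intercept", "none")
      for (rd in reds) {
        if (!rd %in% names(fits)) next
        lt <- lrt_random(best, fits[[rd]])
        lrt_rows[[rd]] <- data.frame(full = best$random, reduced = rd,
                                     statistic = lt$statistic, df = lt$df,
                                     p = lt$p_value, stringsAsFactors = FALSE)
      }
    }
    skill <- predictive_skill(best, nsim = config$glmm$nsim_band,
                              seed = config$seed)
    utils::write.csv(vf$dropped, file.path(outdir, "glmm_vif_dropped.csv"),
                     row.names = FALSE)
    utils::write.csv(utils::head(enum$table, 25),
                     file.path(outdir, "glmm_enumeration.csv"),
                     row.names = FALSE)
    ranef <- data.frame(structure = best$random,
                        term = names(best$ranef_var),
                        variance = as.numeric(best$ranef_var),
                        stringsAsFactors = FALSE)
    utils::write.csv(best$coefficients,
                     file.path(outdir, "glmm_coefficients.csv"),
                     row.names = FALSE)
    utils::write.csv(ranef, file.path(outdir, "glmm_random.csv"),
                     row.names = FALSE)
    if (length(lrt_rows))
      utils::write.csv(do.call(rbind, lrt_rows),
                       file.path(outdir, "glmm_lrt.csv"), row.names = FALSE)
    else
      utils::write.csv(data.frame(full = character(), reduced = character(),
                                  statistic = numeric(), df = numeric(),
                                  p = numeric()),
                       file.path(outdir, "glmm_lrt.csv"), row.names = FALSE)
    utils::write.csv(skill$band, file.path(outdir, "glmm_band.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(window = config$glmm$window, fixed = best$fixed,
           random = best$random, shape = best$shape, aicc = best$aicc,
           loglik = best$loglik, n = best$n,
           marginal_r2 = skill$marginal_r2, adj_r2 = skill$adj_r2,
           chron_r = skill$chron_r, chron_p = skill$chron_p),
      file.path(outdir, "glmm_skill.json"), auto_unbox = TRUE, digits = NA)
    list(files = c("glmm_vif_dropped.csv", "glmm_enumeration.csv",
                   "glmm_coefficients.csv", "glmm_random.csv",
                   "glmm_lrt.csv", "glmm_band.csv", "glmm_skill.json"))
  })

  all_files <- unlist(lapply(manifest$stages, function(s) s$outputs))
  hashes <- tools::md5sum(file.path(outdir, all_files))
  manifest$files <- stats::setNames(as.list(unname(hashes)), all_files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

# config echo for the manifest: plain named lists, no environments; run
# locations (outdir, input paths) are excluded so that reruns of the same
# analysis are manifest-identical wherever they land
config_echo <- function(config) {
  e <- unclass(config)
  e$outdir <- NULL
  e$inputs <- NULL
  if (inherits(e$scenario, "forest_scenario"))
    e$scenario <- unclass(e$scenario)
  e
}

#' Shape stage outputs into the standard report tables
#'
#' Reads a completed run directory and returns the four report tables:
#' BAI chronology characteristics per group and window (trees, spans,
#' interseries r, EPS, mean +/- SD, slope), the d13C/iWUE chronology
#' statistics, the inter-chronology correlation matrix (raw and high-pass),
#' and the growth-model coefficient table. Missing stage outputs yield
#' `NULL` entries with a warning.
#'
#' @param outdir A directory written by [run_pipeline()].
#' @return List with `chronology_stats`, `iwue_stats`,
#'   `chronology_correlations`, `glmm_coefficients`.
#' @export
report <- function(outdir) {
  rd <- function(f) {
    p <- file.path(outdir, f)
    if (!file.exists(p)) {
      warning("report: missing stage output ", f, call. = FALSE)
      return(NULL)
    }
    utils::read.csv(p)
  }
  list(chronology_stats = rd("chron_stats.csv"),
       iwue_stats = rd("iwue_stats.csv"),
       chronology_correlations = rd("chron_corr.csv"),
       glmm_coefficients = rd("glmm_coefficients.csv"))
}
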