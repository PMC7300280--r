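# CSV readers for tree metadata, isotope series, atmospheric history and
# monthly climate, each validating into the pipeline's domain contracts.

GROUP_LEVELS <- c("QuPe", "QuHy", "QuPy")

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) abort(what, " file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort(what, " file ", path, " is missing column(s): ",
          paste(missing, collapse = ", "))
  df
}

check_numeric <- function(df, cols, what) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))
      if (length(bad))
        abort(what, ": non-numeric values in column '", cl, "' at row(s) ",
              paste(utils::head(bad, 5), collapse = ", "))
      df[[cl]] <- coerced
    }
    if (anyNA(df[[cl]]))
      abort(what, ": missing values in column '", cl, "'")
  }
  df
}

#' Read tree metadata
#'
#' Expects columns `tree_id`, `group`, `dbh` (cm) and `height` (m). Tree ids
#' must be unique, sizes strictly positive, and groups drawn from the three
#' genetic group labels.
#'
#' @param path CSV path.
#' @param groups Allowed group labels.
#' @return A validated data frame of tree metadata.
#' @export
read_tree_meta <- function(path, groups = GROUP_LEVELS) {
  df <- read_csv_checked(path, c("tree_id", "group", "dbh", "height"),
                         "tree metadata")
  df <- check_numeric(df, c("dbh", "height"), "tree metadata")
  df$tree_id <- as.character(df$tree_id)
  dup <- unique(df$tree_id[duplicated(df$tree_id)])
  if (length(dup))
    abort("tree metadata: duplicated tree_id(s): ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(df$group), groups)
  if (length(bad))
    abort("tree metadata: unknown group label(s): ", paste(bad, collapse = ", "),
          " (expected ", paste(groups, collapse = "/"), ")")
  if (any(df$dbh <= 0)) abort("tree metadata: dbh must be > 0")
  if (any(df$height <= 0)) abort("tree metadata: height must be > 0")
  df
}

#' Read per-tree annual wood d13C series
#'
#' Expects columns `tree_id`, `year`, `d13c` (permil vs VPDB). Values must
#' lie in the plausible plant range (-35, -10) permil and (tree, year) pairs
#' must be unique. If `meta` is given, isotope tree ids must be a subset of
#' the metadata ids.
#'
#' @param path CSV path.
#' @param meta Optional tree metadata from [read_tree_meta()].
#' @return A long data frame `tree_id`, `year`, `d13c` (plus `group` when
#'   `meta` is supplied).
#' @export
read_isotope_series <- function(path, meta = NULL) {
  df <- read_csv_checked(path, c("tree_id", "year", "d13c"), "isotope")
  df <- check_numeric(df, c("year", "d13c"), "isotope")
  df$tree_id <- as.character(df$tree_id)
  key <- paste(df$tree_id, df$year)
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    abort("isotope: duplicated (tree, year) record(s): ",
          paste(utils::head(dup, 5), collapse = "; "))
  out_of_range <- df$d13c <= -35 | df$d13c >= -10
  if (any(out_of_range))
    abort("isotope: d13C outside the plausible plant range (-35, -10) permil ",
          "for: ", paste(utils::head(
            sprintf("%s@%d (%.1f)", df$tree_id[out_of_range],
                    df$year[out_of_range], df$d13c[out_of_range]), 5),
            collapse = "; "))
  if (!is.null(meta)) {
    unknown <- setdiff(unique(df$tree_id), meta$tree_id)
    if (length(unknown))
      abort("isotope: tree id(s) absent from metadata: ",
            paste(unknown, collapse = ", "))
    df$group <- meta$group[match(df$tree_id, meta$tree_id)]
  }
  df[order(df$tree_id, df$year), , drop = FALSE]
}

#' Read the atmospheric CO2 history
#'
#' Expects columns `year`, `ca` (ppm) and `d13c_atm` (permil). Years must be
#' consecutive and Ca strictly positive.
#'
#' @param path CSV path.
#' @return A data frame `year`, `ca`, `d13c_atm` sorted by year.
#' @export
read_atmosphere <- function(path) {
  df <- read_csv_checked(path, c("year", "ca", "d13c_atm"), "atmosphere")
  df <- check_numeric(df, c("year", "ca", "d13c_atm"), "atmosphere")
  df <- df[order(df$year), , drop = FALSE]
  if (any(df$ca <= 0)) abort("atmosphere: Ca must be > 0")
  if (nrow(df) > 1 && any(diff(df$year) != 1))
    abort("atmosphere: years must be consecutive")
  rownames(df) <- NULL
  df
}

#' Read a monthly climate record
#'
#' Expects columns `year`, `month`, `tmean` (deg C) and `psum` (mm).
#' Precipitation must be non-negative; months outside 1-12 are an error and
#' incomplete years inside the covered span are flagged with a warning.
#'
#' @param path CSV path.
#' @return A data frame `year`, `month`, `tmean`, `psum` sorted by time.
#' @export
read_monthly_climate <- function(path) {
  df <- read_csv_checked(path, c("year", "month", "tmean", "psum"), "climate")
  df <- check_numeric(df, c("year", "month", "tmean", "psum"), "climate")
  if (any(df$month < 1 | df$month > 12))
    abort("climate: month values must be in 1..12")
  if (any(df$psum < 0)) abort("climate: psum must be >= 0")
  key <- paste(df$year, df$month)
  if (anyDuplicated(key))
    abort("climate: duplicated (year, month) records")
  df <- df[order(df$year, df$month), , drop = FALSE]
  span <- seq(min(df$year), max(df$year))
  have <- table(factor(df$year, levels = span))
  gaps <- names(have)[have < 12]
  if (length(gaps))
    warning("climate record has incomplete year(s): ",
            paste(utils::head(gaps, 10), collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Cross-validate a loaded dataset
#'
#' Single entry point checking consistency across the input files: every
#' ring series id appears in the metadata (and vice versa), isotope trees
#' are a subset of the metadata, the atmosphere covers the isotope years and
#' both analysis windows, and the climate record covers the windows.
#'
#' @param rings List of [ring_series()] from [read_rwl()].
#' @param meta Tree metadata.
#' @param isotopes Optional isotope series.
#' @param atmosphere Optional atmospheric record.
#' @param climate Optional monthly climate record.
#' @param windows Optional list of analysis windows (year ranges).
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_dataset <- function(rings, meta, isotopes = NULL, atmosphere = NULL,
                             climate = NULL, windows = NULL) {
  ring_ids <- vapply(rings, function(s) s$tree_id, character(1))
  miss <- setdiff(ring_ids, meta$tree_id)
  if (length(miss))
    abort("validate: ring series without metadata: ", paste(miss, collapse = ", "))
  miss <- setdiff(meta$tree_id, ring_ids)
  if (length(miss))
    abort("validate: metadata trees without ring series: ",
          paste(miss, collapse = ", "))
  if (!is.null(isotopes)) {
    unknown <- setdiff(unique(isotopes$tree_id), meta$tree_id)
    if (length(unknown))
      abort("validate: isotope trees absent from metadata: ",
            paste(unknown, collapse = ", "))
    if (!is.null(atmosphere)) {
      outside <- setdiff(unique(isotopes$year), atmosphere$year)
      if (length(outside))
        abort("validate: isotope year(s) outside atmospheric record: ",
              paste(utils::head(outside, 10), collapse = ", "))
    }
  }
  for (w in windows %||% list()) {
    if (!is.null(atmosphere) &&
        !all(seq(min(w), max(w)) %in% atmosphere$year))
      abort("validate: atmospheric record does not cover window ",
            min(w), "-", max(w))
    if (!is.null(climate) && !all(seq(min(w), max(w)) %in% climate$year))
      abort("validate: climate record does not cover window ",
            min(w), "-", max(w))
  }
  invisible(TRUE)
}
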