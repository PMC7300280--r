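#' A single tree's dated ring-width series
#'
#' The primitive growth record: annual ring widths in mm for strictly
#' consecutive calendar years. A ring labelled year Y is the ring formed in
#' the growing season of year Y (northern-hemisphere convention; no Schulman
#' shift). Missing rings encoded as width 0 are legal and retained.
#'
#' @param tree_id Series identifier (string, at most 8 characters for RWL
#'   round-tripping).
#' @param first_year Calendar year of the first ring.
#' @param widths Numeric vector of ring widths in mm, one per year; finite
#'   and non-negative.
#' @param group Optional group label attached to the tree.
#' @return An object of class `ring_series`.
#' @export
ring_series <- function(tree_id, first_year, widths, group = NA_character_) {
  tree_id <- as.character(tree_id)
  first_year <- as.integer(first_year)
  widths <- as.numeric(widths)
  if (length(tree_id) != 1L || !nzchar(tree_id))
    abort("tree_id must be a non-empty string")
  if (length(widths) < 1L)
    abort("ring series '", tree_id, "' must contain at least one ring")
  if (any(!is.finite(widths)))
    abort("ring series '", tree_id, "' has non-finite widths")
  if (any(widths < 0))
    abort("ring series '", tree_id, "' has negative widths")
  structure(
    list(tree_id = tree_id, group = as.character(group),
         first_year = first_year, widths = widths),
    class = "ring_series")
}

#' @export
print.ring_series <- function(x, ...) {
  cat(sprintf("<ring_series> %s [%d-%d], %d rings, mean width %.3f mm\n",
              x$tree_id, x$first_year, x$first_year + length(x$widths) - 1L,
              length(x$widths), mean(x$widths)))
  invisible(x)
}

#' Years covered by a ring series
#' @param x A `ring_series`.
#' @return Integer vector of calendar years.
#' @export
series_years <- function(x) {
  x$first_year + seq_along(x$widths) - 1L
}

#' Read a Tucson/RWL decadal ring-width file
#'
#' Parses the decadal Tucson layout: each line carries a series id, the year
#' of the line's first value, and up to ten integer widths. The measurement
#' unit is inferred per series from the terminator: 999 closes a 0.01 mm
#' series, -9999 a 0.001 mm series. Widths are returned in mm. Up to three
#' leading header lines (whose second field is not a year) are skipped.
#'
#' @param path Path to the RWL file.
#' @return A named list of [ring_series()] objects.
#' @export
read_rwl <- function(path) {
  if (!file.exists(path)) abort("RWL file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  series_order <- character()
  vals <- list()    # raw integer values per series, in file order
  first <- list()   # first year per series
  count <- list()   # number of values read so far per series

  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    tok <- strsplit(line, "\\s+")[[1]]
    if (length(tok) < 2L)
      abort("malformed RWL line ", i, ": fewer than two fields")
    id <- tok[[1]]
    year <- suppressWarnings(as.integer(tok[[2]]))
    if (is.na(year)) {
      if (i <= 3L && !(id %in% series_order)) next  # header line
      abort("malformed RWL decade line ", i, ": '", tok[[2]],
            "' is not a year")
    }
    v <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (anyNA(v))
      abort("malformed RWL line ", i, ": non-numeric width value")
    if (!(id %in% series_order)) {
      series_order <- c(series_order, id)
      vals[[id]] <- numeric()
      first[[id]] <- year
      count[[id]] <- 0L
    } else {
      expected <- first[[id]] + count[[id]]
      if (year != expected)
        abort("RWL line ", i, ": series '", id, "' year label ", year,
              " does not follow previous rings (expected ", expected, ")")
    }
    vals[[id]] <- c(vals[[id]], v)
    count[[id]] <- count[[id]] + length(v)
  }

  if (!length(series_order)) abort("no series found in ", path)
  out <- lapply(series_order, function(id) {
    v <- vals[[id]]
    n <- length(v)
    if (n < 2L)
      abort("series '", id, "' has no data before its terminator")
    term <- v[[n]]
    scale <- if (term == -9999) 0.001
    else if (term == 999) 0.01
    else abort("series '", id, "' lacks a 999/-9999 terminator (last value ",
               term, ")")
    w <- v[-n]
    if (any(w < 0))
      abort("series '", id, "' has negative widths")
    ring_series(id, first[[id]], w * scale)
  })
  names(out) <- series_order
  out
}

#' Write ring series to a Tucson/RWL decadal file
#'
#' Inverse of [read_rwl()]: values are stored as integers at the declared
#' precision, lines break at decade boundaries, and each series ends with
#' the dialect's terminator (-9999 for 0.001 mm, 999 for 0.01 mm).
#'
#' @param x A `ring_series` or list of them.
#' @param path Output path.
#' @param precision Measurement unit, `"0.001"` (default) or `"0.01"` mm.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(x, path, precision = c("0.001", "0.01")) {
  precision <- match.arg(precision)
  scale <- if (precision == "0.001") 1000 else 100
  term <- if (precision == "0.001") -9999 else 999
  if (inherits(x, "ring_series")) x <- list(x)
  out <- character()
  for (s in x) {
    v <- c(round(s$widths * scale), term)
    yrs <- s$first_year + seq_along(v) - 1L  # terminator takes the next slot
    start <- 1L
    while (start <= length(v)) {
      decade_end <- (yrs[start] %/% 10L) * 10L + 9L
      idx <- start:min(length(v), start + (decade_end - yrs[start]))
      out <- c(out, paste0(sprintf("%-8s", substr(s$tree_id, 1, 8)),
                           sprintf("%4d", yrs[start]),
                           paste0(sprintf("%6d", v[idx]), collapse = "")))
      start <- idx[length(idx)] + 1L
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Convert ring series to a long data frame
#' @param x A list of `ring_series`.
#' @return A data frame with columns `tree_id`, `year`, `width_mm`.
#' @export
rwl_to_long <- function(x) {
  if (inherits(x, "ring_series")) x <- list(x)
  do.call(rbind, lapply(x, function(s) {
    data.frame(tree_id = s$tree_id, year = series_years(s),
               width_mm = s$widths, stringsAsFactors = FALSE)
  }))
}
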