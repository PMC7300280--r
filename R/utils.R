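# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the random seed, runs `code`, and restores the previous RNG state so
#' that callers (simulations, tests, the pipeline) do not perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# stop() without the call, used for user-facing validation errors
abort <- function(...) stop(..., call. = FALSE)

# restrict a (year, value) data frame to a window given as c(first, last)
# or an integer vector of years; NULL means no restriction
window_years <- function(years, window) {
  if (is.null(window)) return(rep(TRUE, length(years)))
  if (length(window) == 2L) years >= min(window) & years <= max(window)
  else years %in% window
}

# normalise a window argument to c(first, last)
as_window <- function(window) {
  if (is.null(window)) return(NULL)
  c(min(window), max(window))
}

# two-sided p-value for a Pearson correlation via the t approximation
cor_p_value <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  r <- min(max(r, -1), 1)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
}

# critical |r| at two-sided level alpha for sample size n
cor_critical <- function(n, alpha = 0.05) {
  if (n < 3) return(NA_real_)
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}
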