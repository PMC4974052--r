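#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state so callers' RNG streams are unaffected. With
#' `seed = NULL` the expression is evaluated against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Half-open [start, end) membership for event times on a shared time base.
in_window <- function(t, window) {
  t >= window[1] & t < window[2]
}

check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 2L || !all(is.finite(window))) {
    stop("'window' must be a finite numeric vector c(start, end)")
  }
  if (window[2] <= window[1]) {
    stop("'window' must satisfy end > start (half-open [start, end))")
  }
  invisible(window)
}

# Relative/absolute comparison tolerance used when counting permutation
# statistics at least as extreme as the observed one.
stat_tol <- function(x) if (is.finite(x)) 1e-8 * (1 + abs(x)) else 0
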