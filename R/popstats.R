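#' Proportion of significant results
#'
#' @param p Vector of p-values from one context/task/window.
#' @param alpha Significance criterion.
#' @param context,task Optional labels carried into the summary.
#' @return An object of class `proportion_summary` with `k`, `n`,
#'   `proportion`, `alpha`, `context`, `task`.
#' @export
proportion_significant <- function(p, alpha = 0.05, context = NA_character_,
                                   task = NA_integer_) {
  if (!length(p)) stop("no results")
  k <- sum(p < alpha)
  structure(
    list(k = k, n = length(p), proportion = k / length(p), alpha = alpha,
         context = context, task = task),
    class = "proportion_summary"
  )
}

#' @export
print.proportion_summary <- function(x, ...) {
  lab <- if (!is.na(x$context)) paste0(" [", x$context,
                                       if (!is.na(x$task)) paste0(", task ", x$task),
                                       "]") else ""
  cat(sprintf("Significant%s: %d/%d = %.1f%% at alpha %g\n", lab,
              x$k, x$n, 100 * x$proportion, x$alpha))
  invisible(x)
}

#' Contrast the prevalence of significant results between contexts
#'
#' One-tailed chi-square comparing the proportion of significant units/sites
#' between two behavioral contexts (e.g. correct performance vs passive
#' listening), testing whether the first is larger. When the two summaries
#' come from the same units (correct vs error trials of one session), the
#' independence assumption of the chi-square is only approximate; this is
#' flagged, not prevented.
#'
#' @param summary_a,summary_b [proportion_significant()] summaries; the test
#'   direction is `a` greater.
#' @param independent Set to `FALSE` to flag overlapping unit sets.
#' @return A [chisq_one_tailed()] result with an `independent` flag.
#' @export
context_contrast <- function(summary_a, summary_b, independent = TRUE) {
  stopifnot(inherits(summary_a, "proportion_summary"),
            inherits(summary_b, "proportion_summary"))
  res <- chisq_one_tailed(summary_a$k, summary_a$n, summary_b$k, summary_b$n,
                          direction = "first_greater")
  res$independent <- independent
  res
}

#' Contrast significance prevalence between delay durations
#'
#' Tests whether load effects are more prevalent with the shorter delay, as
#' expected if they were decaying stimulus-evoked (late) activity rather than
#' persistent storage: a one-tailed chi-square of the short-delay proportion
#' being greater than the long-delay proportion. Persistent effects yield a
#' non-significant contrast; decaying effects a significant one.
#'
#' @param results_short,results_long P-value vectors (or
#'   `proportion_summary` objects) from the final 500 ms of the shorter and
#'   longer delay.
#' @param alpha Criterion applied when p-value vectors are supplied.
#' @return A [chisq_one_tailed()] result.
#' @export
delay_duration_contrast <- function(results_short, results_long,
                                    alpha = 0.05) {
  as_summary <- function(r) {
    if (inherits(r, "proportion_summary")) r
    else proportion_significant(r, alpha)
  }
  a <- as_summary(results_short)
  b <- as_summary(results_long)
  chisq_one_tailed(a$k, a$n, b$k, b$n, direction = "first_greater")
}
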