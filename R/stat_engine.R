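#' Configuration of a permutation test
#'
#' @param n_permutations Number of Monte-Carlo permutations (>= 1); ignored
#'   when the test enumerates exhaustively.
#' @param tail `"two"`, `"one_greater"` or `"one_less"`.
#' @param statistic Test statistic: `"log_ratio_of_means"`,
#'   `"difference_of_means"`, `"difference_of_medians"` (two-sample tests) or
#'   `"paired_signflip_mean"` (paired tests).
#' @param exhaustive `"auto"` enumerates all label assignments when their
#'   number is at most `exhaustive_limit` (two-sample) or `2^n <= 2^13`
#'   (sign-flip); `"never"`/`"always"` force the choice.
#' @param exhaustive_limit Assignment-count threshold for `"auto"`.
#' @param seed Optional seed for the Monte-Carlo draws.
#' @return A list of class `perm_config`.
#' @export
perm_config <- function(n_permutations = 2000,
                        tail = c("two", "one_greater", "one_less"),
                        statistic = c("log_ratio_of_means",
                                      "difference_of_means",
                                      "difference_of_medians",
                                      "paired_signflip_mean"),
                        exhaustive = c("auto", "never", "always"),
                        exhaustive_limit = 1e4, seed = NULL) {
  if (n_permutations < 1) stop("'n_permutations' must be >= 1")
  structure(
    list(n_permutations = as.integer(n_permutations),
         tail = match.arg(tail), statistic = match.arg(statistic),
         exhaustive = match.arg(exhaustive),
         exhaustive_limit = exhaustive_limit, seed = seed),
    class = "perm_config"
  )
}

# Count of permutation statistics at least as extreme as the observed one,
# under the configured tail, with a numerical tie tolerance.
tail_p <- function(stats_perm, obs, tail, add_one) {
  tol <- stat_tol(obs)
  hits <- switch(tail,
    two = abs(stats_perm) >= abs(obs) - tol,
    one_greater = stats_perm >= obs - tol,
    one_less = stats_perm <= obs + tol
  )
  if (add_one) (1 + sum(hits)) / (length(stats_perm) + 1) else mean(hits)
}

# Two-sample statistics expressed through per-group sums (means) so the
# Monte-Carlo path vectorizes; the log-ratio guard adds eps to both means
# when either is non-positive, preserving the ratio's direction.
two_sample_stat <- function(statistic, eps) {
  switch(statistic,
    log_ratio_of_means = function(m1, m2) {
      fix <- m1 <= 0 | m2 <= 0
      m1[fix] <- m1[fix] + eps
      m2[fix] <- m2[fix] + eps
      out <- log(m1 / m2)
      out[m1 == 0 & m2 == 0] <- 0
      out
    },
    difference_of_means = function(m1, m2) m1 - m2,
    stop("not a mean-based statistic: ", statistic)
  )
}

#' Two-sample permutation test
#'
#' Tests whether per-trial values in two condition groups differ, by shuffling
#' the condition labels. The observed statistic is computed on the true
#' labels; the null distribution by re-splitting the pooled values into groups
#' of the original sizes. When the number of distinct label assignments is
#' small (at most `exhaustive_limit`, default 10^4) all assignments are
#' enumerated; otherwise Monte-Carlo resampling with the add-one rule
#' `p = (1 + #extreme) / (n_perm + 1)` is used, so `p >= 1/(n_perm+1)` and
#' `p = 0` never occurs.
#'
#' @param x,y Per-trial values of the two groups (each length >= 2).
#' @param config A [perm_config()]; `statistic` must be one of
#'   `"log_ratio_of_means"`, `"difference_of_means"`,
#'   `"difference_of_medians"`.
#' @param eps Guard added to both group means when either is non-positive and
#'   the statistic is a log ratio (see [load_ratio()] for the rate rule).
#' @return An object of class `perm_result` with fields `statistic`,
#'   `p_value`, `n_x`, `n_y`, `method`, `tail`, `n_permutations`,
#'   `exhaustive`.
#' @examples
#' perm_test_two_sample(c(2, 4), c(0, 1),
#'   perm_config(statistic = "difference_of_means"))$p_value  # 1/3
#' @export
perm_test_two_sample <- function(x, y, config = perm_config(), eps = 0) {
  stopifnot(inherits(config, "perm_config"))
  if (length(x) < 2 || length(y) < 2) stop("both groups need >= 2 values")
  if (config$statistic == "paired_signflip_mean") {
    stop("use perm_test_signflip() for paired data")
  }
  z <- c(x, y)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  median_stat <- config$statistic == "difference_of_medians"

  stat_of <- if (median_stat) {
    function(a, b) stats::median(a) - stats::median(b)
  } else {
    f <- two_sample_stat(config$statistic, eps)
    function(a, b) f(mean(a), mean(b))
  }
  obs <- stat_of(x, y)

  n_assign <- choose(n, n1)
  use_exhaustive <- switch(config$exhaustive,
    auto = n_assign <= config$exhaustive_limit,
    always = TRUE, never = FALSE
  )

  if (use_exhaustive) {
    sel <- utils::combn(n, n1)
    stats_perm <- apply(sel, 2, function(i) stat_of(z[i], z[-i]))
    p <- tail_p(stats_perm, obs, config$tail, add_one = FALSE)
    n_used <- ncol(sel)
  } else {
    # The permutation null depends only on the pooled multiset, so the pool
    # is canonicalized (sorted) before drawing: with equal group sizes and a
    # fixed seed, swapping the two groups then reproduces the identical null
    # set and hence the identical two-tailed p.
    zs <- sort(z)
    stats_perm <- with_seed(config$seed, {
      B <- config$n_permutations
      idx <- vapply(seq_len(B), function(b) sample.int(n, n1), integer(n1))
      if (median_stat) {
        apply(idx, 2, function(i) stat_of(zs[i], zs[-i]))
      } else {
        f <- two_sample_stat(config$statistic, eps)
        m1 <- colSums(matrix(zs[idx], nrow = n1)) / n1
        m2 <- (sum(zs) - m1 * n1) / n2
        f(m1, m2)
      }
    })
    p <- tail_p(stats_perm, obs, config$tail, add_one = TRUE)
    n_used <- config$n_permutations
  }

  structure(
    list(statistic = obs, p_value = p, n_x = n1, n_y = n2,
         method = config$statistic, tail = config$tail,
         n_permutations = n_used, exhaustive = use_exhaustive),
    class = "perm_result"
  )
}

#' Paired sign-flip permutation test
#'
#' Tests whether paired differences (per unit or per subject) have mean zero
#' by randomly flipping their signs. All `2^n` flips are enumerated when
#' `n <= 13`; otherwise Monte-Carlo flips with the add-one rule.
#'
#' @param d Paired differences (length >= 2).
#' @param config A [perm_config()]; the statistic is the mean of `d`.
#' @return A `perm_result` (with `n_x = length(d)`).
#' @examples
#' perm_test_signflip(rep(1, 12))$p_value  # 2/4096, exhaustive
#' @export
perm_test_signflip <- function(d, config = perm_config()) {
  stopifnot(inherits(config, "perm_config"))
  n <- length(d)
  if (n < 2) stop("need >= 2 paired differences")
  obs <- mean(d)

  use_exhaustive <- switch(config$exhaustive,
    auto = n <= 13, always = TRUE, never = FALSE
  )
  if (use_exhaustive) {
    signs <- matrix(1, 2^n, n)
    for (j in seq_len(n)) {
      signs[, j] <- ifelse(bitwAnd(seq_len(2^n) - 1L, bitwShiftL(1L, j - 1L)) > 0,
                           -1, 1)
    }
    stats_perm <- as.vector(signs %*% d) / n
    p <- tail_p(stats_perm, obs, config$tail, add_one = FALSE)
    n_used <- 2^n
  } else {
    stats_perm <- with_seed(config$seed, {
      B <- config$n_permutations
      s <- matrix(sample(c(-1, 1), B * n, replace = TRUE), B, n)
      as.vector(s %*% d) / n
    })
    p <- tail_p(stats_perm, obs, config$tail, add_one = TRUE)
    n_used <- config$n_permutations
  }

  structure(
    list(statistic = obs, p_value = p, n_x = n, n_y = n,
         method = "paired_signflip_mean", tail = config$tail,
         n_permutations = n_used, exhaustive = use_exhaustive),
    class = "perm_result"
  )
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %s-tailed%s)\n", x$method,
              if (x$tail == "two") "two" else "one",
              if (x$exhaustive) ", exhaustive" else ""))
  cat(sprintf("  statistic = %.4g, p = %.4g (n = %d vs %d, %d assignments)\n",
              x$statistic, x$p_value, x$n_x, x$n_y, x$n_permutations))
  invisible(x)
}

#' One-tailed chi-square test for two proportions
#'
#' Pearson 2x2 chi-square without continuity correction, converted to a
#' one-tailed p-value: `p_two/2` when the observed direction matches the
#' hypothesized one, `1 - p_two/2` otherwise, and 0.5 at exactly equal
#' proportions.
#'
#' @param k1,n1 Successes and total in the group hypothesized larger (under
#'   `direction = "first_greater"`).
#' @param k2,n2 Successes and total in the other group.
#' @param direction `"first_greater"` or `"first_less"`.
#' @return List with `statistic` (chi-square), `p_value`, `proportions`.
#' @examples
#' chisq_one_tailed(9, 10, 1, 10)$statistic  # 12.8
#' @export
chisq_one_tailed <- function(k1, n1, k2, n2,
                             direction = c("first_greater", "first_less")) {
  direction <- match.arg(direction)
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be > 0")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("need 0 <= k <= n")
  a <- k1; b <- n1 - k1; cc <- k2; d <- n2 - k2
  n <- n1 + n2
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  chi2 <- if (denom == 0) 0 else n * (a * d - b * cc)^2 / denom
  p_two <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  diff <- k1 / n1 - k2 / n2
  p <- if (diff == 0) {
    0.5
  } else if ((diff > 0) == (direction == "first_greater")) {
    p_two / 2
  } else {
    1 - p_two / 2
  }
  list(statistic = chi2, p_value = p,
       proportions = c(k1 / n1, k2 / n2), direction = direction)
}

#' Bonferroni correction
#'
#' @param p Vector of p-values.
#' @param m Number of tests corrected for (must be at least `length(p)`).
#' @param alpha Family-wise significance level.
#' @return List with `p_adjusted` (`min(1, m * p)`), `significant`
#'   (`p < alpha / m`), `m`, `alpha`.
#' @export
bonferroni <- function(p, m = length(p), alpha = 0.05) {
  if (m < 1) stop("'m' must be >= 1")
  if (m < length(p)) stop("'m' must be at least the number of tests")
  list(p_adjusted = pmin(1, m * p), significant = p < alpha / m,
       m = m, alpha = alpha)
}
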