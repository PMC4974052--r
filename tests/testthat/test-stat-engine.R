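test_that("two-sample permutation test matches the enumeration oracle", {
  # all 6 equal splits of {2,4,0,1}: |mean diff| >= 2.5 for exactly 2 of them
  res <- perm_test_two_sample(c(2, 4), c(0, 1),
                              perm_config(statistic = "difference_of_means"))
  expect_true(res$exhaustive)
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$statistic, 2.5)

  # identical constant groups: zero statistic, p = 1
  res0 <- perm_test_two_sample(rep(3, 4), rep(3, 4), perm_config())
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  expect_error(perm_test_two_sample(1, c(1, 2), perm_config()), ">= 2")
})

test_that("exhaustive and Monte-Carlo p-values agree within sampling error", {
  set.seed(101)
  x <- rnorm(6, 1)
  y <- rnorm(6)
  pe <- perm_test_two_sample(x, y,
    perm_config(statistic = "difference_of_means", exhaustive = "always"))
  pm <- perm_test_two_sample(x, y,
    perm_config(4000, statistic = "difference_of_means", exhaustive = "never",
                seed = 7))
  se <- sqrt(pe$p_value * (1 - pe$p_value) / 4000)
  expect_lt(abs(pe$p_value - pm$p_value), 2 * se + 1 / 4001)
})

test_that("p-values are invariant under group exchange with sign flip", {
  set.seed(102)
  x <- rpois(5, 6)
  y <- rpois(5, 3)
  for (stat in c("difference_of_means", "log_ratio_of_means",
                 "difference_of_medians")) {
    cfg <- perm_config(statistic = stat, exhaustive = "always")
    a <- perm_test_two_sample(x, y, cfg, eps = 0.1)
    b <- perm_test_two_sample(y, x, cfg, eps = 0.1)
    expect_equal(a$p_value, b$p_value)
    expect_equal(a$statistic, -b$statistic)
  }
})

test_that("Monte-Carlo p-values respect the add-one floor", {
  set.seed(103)
  res <- perm_test_two_sample(rnorm(50, 10), rnorm(50, 0),
    perm_config(500, statistic = "difference_of_means"))
  expect_false(res$exhaustive)
  expect_equal(res$p_value, 1 / 501)
})

test_that("sign-flip test enumerates exhaustively and handles boundaries", {
  expect_equal(perm_test_signflip(rep(0, 8))$p_value, 1)
  # 12 equal positive values: only the all-plus and all-minus assignments
  # reach |mean| >= observed
  res <- perm_test_signflip(rep(2.5, 12))
  expect_true(res$exhaustive)
  expect_equal(res$p_value, 2 / 4096)
  one <- perm_test_signflip(rep(2.5, 12), perm_config(tail = "one_greater"))
  expect_equal(one$p_value, 1 / 4096)
  expect_error(perm_test_signflip(1), ">= 2")
})

test_that("sign-flip p-values are uniform under the null", {
  set.seed(104)
  p <- replicate(400, perm_test_signflip(rnorm(12))$p_value)
  # the exhaustive p lattice has ties; ks.test warns about them but the
  # uniformity check itself is what matters here
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("type-I error is near nominal for the two-sample test", {
  set.seed(105)
  p <- replicate(400, {
    perm_test_two_sample(rpois(20, 5), rpois(20, 5),
      perm_config(300, statistic = "log_ratio_of_means",
                  exhaustive = "never"), eps = 0.05)$p_value
  })
  rate <- mean(p < 0.05)
  ci_half <- 2.58 * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(rate - 0.05), ci_half + 0.005)
})

test_that("rejection rate grows with effect size and sample size", {
  set.seed(106)
  reject <- function(shift, n) {
    mean(replicate(120, {
      perm_test_two_sample(rnorm(n, shift), rnorm(n),
        perm_config(200, statistic = "difference_of_means",
                    exhaustive = "never"))$p_value < 0.05
    }))
  }
  expect_lt(reject(0, 20), reject(1.2, 20))
  expect_lt(reject(0.8, 10) - 0.1, reject(0.8, 40))
  expect_gt(reject(1.2, 40), 0.9)
})

test_that("one-tailed chi-square reproduces worked values and conventions", {
  res <- chisq_one_tailed(9, 10, 1, 10)
  expect_equal(res$statistic, 12.8)
  expect_lt(res$p_value, 0.001)

  expect_equal(chisq_one_tailed(5, 10, 10, 20)$p_value, 0.5)
  # direction mismatch folds to the upper half
  expect_gt(chisq_one_tailed(1, 10, 9, 10)$p_value, 0.999)
  expect_error(chisq_one_tailed(1, 0, 1, 10), "> 0")
  expect_error(chisq_one_tailed(11, 10, 1, 10), "0 <= k <= n")
})

test_that("one-tailed chi-square is calibrated under equal proportions", {
  set.seed(107)
  p <- replicate(2000, {
    k <- rbinom(2, 50, 0.3)
    chisq_one_tailed(k[1], 50, k[2], 50)$p_value
  })
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("bonferroni matches the closed form and p.adjust", {
  b <- bonferroni(c(0.01, 0.02, 0.2), m = 3)
  expect_identical(b$significant, c(TRUE, FALSE, FALSE))
  expect_equal(b$p_adjusted, stats::p.adjust(c(0.01, 0.02, 0.2), "bonferroni"))
  expect_identical(bonferroni(0.04, m = 1)$significant, TRUE)
  expect_error(bonferroni(0.5, m = 0), ">= 1")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "at least")
})
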