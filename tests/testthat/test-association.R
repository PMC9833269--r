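test_that("quantile assignment uses interpolated cuts with ties going low", {
  expect_equal(assignQuantiles(1:9, 3), rep(1:3, each = 3))
  expect_equal(assignQuantiles(1:8, 4), rep(1:4, each = 2))
  # a value exactly on a cut point joins the lower group
  x <- c(1, 2, 3, 4, 5, 6)  # tertile cuts at 2.667 / 4.333
  expect_equal(assignQuantiles(x, 3), c(1, 1, 2, 2, 3, 3))
  # near-balance at scale: all-distinct scores split within 1 of n/k
  set.seed(5)
  s <- rnorm(1000)
  q <- assignQuantiles(s, 4)
  expect_true(all(abs(tabulate(q, 4) - 250) <= 1))
  expect_true(all(tapply(s, q, max)[1:3] <= tapply(s, q, min)[2:4]))
  expect_error(assignQuantiles(rep(1:2, 5), 3), "distinct")
  expect_error(assignQuantiles(c(1, NA, 2, 3), 3), "NA")
})

test_that("linear association matches the closed-form OLS oracle", {
  # noiseless fit: lm warns about a perfect fit, which is the point here
  r <- suppressWarnings(linearAssoc(2 * (1:20) + 1, 1:20))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r2, 1)
  set.seed(21)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    x <- rnorm(n); y <- rnorm(n, 1 + 0.5 * x, 2)
    r <- linearAssoc(y, x)
    # two-variable least squares in closed form
    bhat <- cov(x, y) / var(x)
    ahat <- mean(y) - bhat * mean(x)
    ss_res <- sum((y - ahat - bhat * x)^2)
    r2 <- 1 - ss_res / sum((y - mean(y))^2)
    expect_equal(r$slope, bhat, tolerance = 1e-8)
    expect_equal(r$intercept, ahat, tolerance = 1e-8)
    expect_equal(r$r2, r2, tolerance = 1e-8)
    expect_equal(r$adjusted_r2, 1 - (1 - r2) * (n - 1) / (n - 2),
                 tolerance = 1e-8)
    expect_lte(r$adjusted_r2, r$r2)
  }
  # null case: slope statistically indistinguishable from zero
  set.seed(22)
  x <- rnorm(1e4); y <- rnorm(1e4)
  r <- linearAssoc(y, x)
  se <- sqrt(sum(residuals(r$fit)^2) / (1e4 - 2) / sum((x - mean(x))^2))
  expect_lt(abs(r$slope), 3 * se)
  expect_error(linearAssoc(1:5, 1:4), "lengths differ")
  expect_error(linearAssoc(rnorm(10), rep(1, 10)), "singular")
})

test_that("adjusted R2 penalizes extra covariates correctly", {
  set.seed(31)
  n <- 200
  x <- rnorm(n); z <- rnorm(n); y <- 100 + 2 * x + rnorm(n, 0, 5)
  r <- linearAssoc(y, x, covariates = data.frame(z = z))
  expect_equal(r$adjusted_r2, 1 - (1 - r$r2) * (n - 1) / (n - 2 - 1),
               tolerance = 1e-10)
})

test_that("quartile logistic model recovers known odds ratios", {
  set.seed(41)
  n <- 6000
  q <- sample(1:4, n, replace = TRUE)
  age <- rnorm(n, 50, 9)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  beta_q4 <- 0.55
  eta <- -2 + beta_q4 * (q == 4) + 0.1 * (age - 50) + 1.2 * (sex == "M")
  y <- runif(n) < plogis(eta)
  r <- logisticQuartileOr(y, q, age, sex)
  q4 <- r$quartile_or[r$quartile_or$quartile == 4, ]
  expect_gt(q4$ci_hi, exp(beta_q4) * 0.99)
  expect_lt(q4$ci_lo, exp(beta_q4) * 1.01)
  expect_equal(r$quartile_or$or[1], 1)
  expect_true(all(r$quartile_or$or[-1] > r$quartile_or$ci_lo[-1] &
                    r$quartile_or$or[-1] < r$quartile_or$ci_hi[-1]))
  age_row <- r$covariates[r$covariates$term == ".age", ]
  expect_lt(abs(log(age_row$or) - 0.1), 0.02)
  expect_gt(r$trend_or$or, 1)
  expect_error(logisticQuartileOr(rep(FALSE, 100), rep(1:4, 25)),
               "constant|classes")
})

test_that("contingency comparisons reproduce the published cohort table", {
  mi <- matrix(c(75, 491 - 75, 46, 193 - 46), nrow = 2, byrow = TRUE)
  r <- groupCompare(mi, test = "chi2")
  expect_equal(r$p_value, 0.011, tolerance = 0.05)
  expect_equal(round(r$p_value, 3), 0.011)
  stroke <- matrix(c(21, 491 - 21, 9, 193 - 9), nrow = 2, byrow = TRUE)
  r2 <- groupCompare(stroke, test = "chi2")
  expect_equal(round(r2$p_value, 2), 0.99)
  # the continuity correction is what reproduces the printed values: the
  # uncorrected statistic would give ~0.008 for the first table
  expect_gt(r$p_value, chisq.test(mi, correct = FALSE)$p.value)
})

test_that("rank tests dispatch by group count and handle degenerate input", {
  r <- groupCompare(rep(1, 10), rep(c("a", "b"), each = 5),
                    test = "mannwhitney")
  expect_equal(r$p_value, 1)
  set.seed(51)
  v <- c(rnorm(40), rnorm(40, 3))
  g <- rep(c("a", "b"), each = 40)
  r2 <- groupCompare(v, g)  # auto -> Mann-Whitney for 2 groups
  expect_identical(r2$test, "Mann-Whitney")
  expect_lt(r2$p_value, 1e-6)
  v3 <- c(rnorm(40), rnorm(40), rnorm(40, 3))
  g3 <- rep(c("a", "b", "c"), each = 40)
  r3 <- groupCompare(v3, g3)  # auto -> Kruskal-Wallis for 3 groups
  expect_identical(r3$test, "Kruskal-Wallis")
  expect_lt(r3$p_value, 1e-6)
  # significant omnibus test triggers Bonferroni-adjusted post-hoc pairs
  expect_false(is.null(r3$posthoc))
  expect_lt(r3$posthoc["c", "a"], 0.05)   # shifted pair stays significant
  expect_gt(r3$posthoc["b", "a"], 0.05)   # null pair does not
  expect_error(groupCompare(rnorm(5), rep("a", 5)), "group")
})

test_that("logistic type-I error is nominal under the null", {
  # 300 replicates at n = 400: fraction of Q4 CIs excluding 1 ~ 5%
  set.seed(61)
  hits <- 0L
  B <- 300L
  for (b in seq_len(B)) {
    q <- rep(1:4, each = 100)
    y <- runif(400) < 0.3
    r <- logisticQuartileOr(y, q)
    q4 <- r$quartile_or[4, ]
    if (q4$ci_lo > 1 || q4$ci_hi < 1) hits <- hits + 1L
  }
  expect_lt(abs(hits / B - 0.05), 0.035)
})
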