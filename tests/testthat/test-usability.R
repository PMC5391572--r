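test_that("score_sus matches the per-item contribution oracle", {
  cases <- list(
    best = rep(c(5L, 1L), 5),     # odd 5 / even 1: everything 100
    mid = rep(3L, 10),            # all 3: everything 50
    all5 = rep(5L, 10)            # all 5: overall 50, learnability 0
  )
  for (nm in names(cases)) {
    got <- score_sus(cases[[nm]])
    want <- oracle_sus(cases[[nm]])
    expect_equal(got$overall, unname(want["overall"]), info = nm)
    expect_equal(got$usability, unname(want["usability"]), info = nm)
    expect_equal(got$learnability, unname(want["learnability"]), info = nm)
  }
  expect_equal(score_sus(cases$best)$overall, 100)
  expect_equal(score_sus(cases$mid)$overall, 50)
  # the spec-resolved all-fives case: identity holds through the oracle
  all5 <- score_sus(cases$all5)
  expect_equal(all5$overall, 50)
  expect_equal(all5$usability, 62.5)
  expect_equal(all5$learnability, 0)
})

test_that("overall = 0.8*usability + 0.2*learnability for random responses", {
  set.seed(31)
  for (i in 1:500) {
    items <- sample(1:5, 10, replace = TRUE)
    s <- score_sus(items)
    expect_equal(s$overall, 0.8 * s$usability + 0.2 * s$learnability)
    want <- oracle_sus(items)
    expect_equal(s$overall, unname(want["overall"]))
  }
})

test_that("score_sus is monotone in the helpful direction", {
  set.seed(77)
  for (i in 1:100) {
    items <- sample(1:5, 10, replace = TRUE)
    base <- score_sus(items)
    j <- sample(10, 1)
    bumped <- items
    if (j %% 2 == 1) bumped[j] <- min(5L, items[j] + 1L)
    else bumped[j] <- max(1L, items[j] - 1L)
    new <- score_sus(bumped)
    expect_gte(new$overall, base$overall)
    expect_gte(new$usability, base$usability)
    expect_gte(new$learnability, base$learnability)
  }
})

test_that("benchmark t-test from summary stats reproduces printed CIs", {
  # mean 92, sd 9, n 14 vs benchmark 68: CI rounds to (87, 97), p < 0.0001
  tr <- sus_ttest_summary(92, 9, 14)
  expect_equal(round(tr$ci_low), 87)
  expect_equal(round(tr$ci_high), 97)
  expect_lt(tr$p_value, 1e-4)
  expect_equal(tr$df, 13)
  # closed-form check of the statistic
  expect_equal(tr$statistic, (92 - 68) / (9 / sqrt(14)))
  # CI against base R's t.test machinery on a matching sample
  x <- scale(rnorm(14))[, 1] * 9 + 92 # mean exactly 92, sd exactly 9
  ref <- t.test(x, mu = 68)
  expect_equal(tr$ci_low, unname(ref$conf.int[1]))
  expect_equal(tr$ci_high, unname(ref$conf.int[2]))
  expect_equal(benchmark_ttest(x)$statistic, unname(ref$statistic))
})

test_that("benchmark t-test edge cases and CI monotonicity", {
  expect_error(benchmark_ttest(rep(68, 5)), "zero variance")
  expect_error(benchmark_ttest(92), "at least 2")
  tr95 <- sus_ttest_summary(92, 9, 14, alpha = 0.05)
  tr80 <- sus_ttest_summary(92, 9, 14, alpha = 0.20)
  expect_lt(tr95$ci_low, tr80$ci_low) # widening alpha narrows the CI
  expect_true(tr95$ci_low <= tr95$estimate & tr95$estimate <= tr95$ci_high)
  # one-sided option
  g <- sus_ttest_summary(92, 9, 14, sides = "greater")
  expect_equal(g$p_value, tr95$p_value / 2)
})

test_that("icc31 agrees with the from-scratch ANOVA oracle", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(3:12, 1); k <- sample(2:8, 1)
    m <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k) +
      rnorm(n) + rep(rnorm(k), each = n)
    expect_equal(icc31(m)$estimate, oracle_icc31(m), tolerance = 1e-10)
  }
})

test_that("icc31 limiting behavior: additive -> 1, pure noise -> ~0", {
  # noiseless additive matrix: perfect consistency
  target <- rnorm(10); rater <- rnorm(14)
  m <- outer(target, rep(1, 14)) + outer(rep(1, 10), rater)
  r <- icc31(m)
  expect_equal(r$estimate, 1)
  # i.i.d. noise only, 100 x 14: |ICC| < 0.1
  set.seed(101)
  m0 <- matrix(rnorm(100 * 14), 100, 14)
  expect_lt(abs(icc31(m0)$estimate), 0.1)
  # degenerate: constant matrix is undefined
  expect_error(icc31(matrix(5, 4, 4)), "undefined")
})

test_that("icc31 is consistency-type: rater column shifts do not change it", {
  set.seed(55)
  m <- matrix(rnorm(10 * 14), 10, 14) + rnorm(10)
  base <- icc31(m)$estimate
  m2 <- m
  m2[, 3] <- m2[, 3] + 100
  expect_equal(icc31(m2)$estimate, base)
  # target relabeling does not change it either
  expect_equal(icc31(m[sample(10), ])$estimate, base)
})

test_that("icc31 CI uses the Shrout-Fleiss F bounds and brackets the estimate", {
  set.seed(21)
  m <- matrix(rnorm(10 * 14, sd = 0.6), 10, 14) + rnorm(10, sd = 1.5)
  r <- icc31(m)
  n <- 10; k <- 14
  f <- r$statistic
  fl <- f / qf(0.975, n - 1, (n - 1) * (k - 1))
  fu <- f * qf(0.975, (n - 1) * (k - 1), n - 1)
  expect_equal(r$ci_low, (fl - 1) / (fl + k - 1))
  expect_equal(r$ci_high, (fu - 1) / (fu + k - 1))
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
})

test_that("summarize_study mirrors the results-table columns", {
  resp <- generate_sus_responses(14, 92, 9, seed = 9)
  tab <- summarize_study(resp, round_ci = TRUE)
  expect_equal(tab$scale, c("overall", "usability", "learnability"))
  expect_equal(tab$n, rep(14L, 3))
  ov <- tab[tab$scale == "overall", ]
  expect_equal(c(ov$ci_low_disp, ov$ci_high_disp), c(87, 97))
  expect_true(all(tab$p < 1e-4))

  expect_error(summarize_study(resp[1]), "at least 2")
  same <- replicate(5, sus_response("r", rep(c(5L, 1L), 5)), simplify = FALSE)
  expect_error(summarize_study(same), "zero variance")
})
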