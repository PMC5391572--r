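#' Construct a System Usability Scale response
#'
#' Ten 5-point Likert items (1 = strongly disagree .. 5 = strongly agree).
#'
#' @param respondent_id Respondent identifier.
#' @param items Integer vector of length 10, entries in 1..5.
#' @return An object of class `sus_response`.
#' @export
sus_response <- function(respondent_id, items) {
  items <- as.integer(items)
  if (length(items) != 10L) stop("a SUS response has exactly 10 items")
  if (any(is.na(items) | items < 1L | items > 5L)) {
    stop("SUS items must be integers in 1..5")
  }
  structure(list(respondent_id = respondent_id, items = items),
            class = "sus_response")
}

#' Score a SUS response
#'
#' Standard 0-100 transform: odd items contribute `rating - 1`, even items
#' `5 - rating`; the overall score is 2.5 times the contribution total. The
#' Lewis-Sauro subscales split the items: learnability is items 4 and 8
#' scaled by 12.5, usability is the remaining eight items scaled by 3.125.
#' These weightings make `overall = 0.8 * usability + 0.2 * learnability`
#' an exact algebraic identity for every possible response.
#'
#' @param response A [sus_response()] (or bare integer vector of 10 items).
#' @return List with `overall`, `usability`, `learnability`, each in
#'   \[0, 100\].
#' @export
score_sus <- function(response) {
  items <- if (inherits(response, "sus_response")) response$items
           else as.integer(response)
  if (length(items) != 10L) stop("a SUS response has exactly 10 items")
  odd <- seq(1L, 9L, by = 2L)
  contrib <- numeric(10L)
  contrib[odd] <- items[odd] - 1L
  contrib[-odd] <- 5L - items[-odd]
  learn_items <- c(4L, 8L)
  list(overall = 2.5 * sum(contrib),
       usability = 3.125 * sum(contrib[-learn_items]),
       learnability = 12.5 * sum(contrib[learn_items]))
}

#' @keywords internal
#' @noRd
test_result <- function(estimate, ci_low, ci_high, statistic, df, p_value,
                        alpha) {
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 statistic = statistic, df = df, p_value = p_value,
                 alpha = alpha),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("estimate %.4g, %d%% CI (%.4g, %.4g), statistic %.4g, df %s, p %.3g\n",
              x$estimate, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              x$statistic, paste(signif(x$df, 6), collapse = ","), x$p_value))
  invisible(x)
}

#' One-sample t-test from summary statistics
#'
#' Core of the benchmark test: `t = (mean - benchmark) / (sd / sqrt(n))` with
#' `n - 1` degrees of freedom. The confidence interval is the usual
#' two-sided `mean ± t(1 - alpha/2, n-1) * sd / sqrt(n)` regardless of test
#' sidedness. The benchmark's literature SD (12.5 for the SUS "highly
#' acceptable" anchor of 68) is not used: a one-sample t relies on the
#' sample SD.
#'
#' @param mean,sd,n Sample summary statistics (`n >= 2`, `sd > 0`).
#' @param benchmark Null-hypothesis mean (default 68).
#' @param alpha Significance level for the CI (default 0.05).
#' @param sides `"two"` (default), `"greater"` or `"less"`.
#' @return A `test_result` with `estimate` (the sample mean), `ci_low`,
#'   `ci_high`, `statistic`, `df`, `p_value`, `alpha`.
#' @export
sus_ttest_summary <- function(mean, sd, n, benchmark = 68, alpha = 0.05,
                              sides = c("two", "greater", "less")) {
  sides <- match.arg(sides)
  if (n < 2) stop("need n >= 2")
  if (!is.finite(sd) || sd <= 0) stop("zero variance: t statistic undefined")
  se <- sd / sqrt(n)
  tstat <- (mean - benchmark) / se
  df <- n - 1
  p <- switch(sides,
              two = 2 * stats::pt(-abs(tstat), df),
              greater = stats::pt(tstat, df, lower.tail = FALSE),
              less = stats::pt(tstat, df))
  half <- stats::qt(1 - alpha / 2, df) * se
  test_result(mean, mean - half, mean + half, tstat, df, p, alpha)
}

#' Benchmark t-test of SUS scores
#'
#' Tests a vector of (transformed, 0-100) scores against the literature
#' benchmark for "highly acceptable" usability, 68.
#'
#' @param scores Numeric vector of scores, `length >= 2`, finite.
#' @param benchmark,alpha,sides As in [sus_ttest_summary()].
#' @return A `test_result`.
#' @export
benchmark_ttest <- function(scores, benchmark = 68, alpha = 0.05,
                            sides = c("two", "greater", "less")) {
  sides <- match.arg(sides)
  if (length(scores) < 2L) stop("need at least 2 scores")
  if (any(!is.finite(scores))) stop("scores must be finite")
  sus_ttest_summary(mean(scores), stats::sd(scores), length(scores),
                    benchmark = benchmark, alpha = alpha, sides = sides)
}

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, consistency, single-rater intraclass correlation
#' (Shrout & Fleiss case 3, single measures):
#' `ICC = (BMS - EMS) / (BMS + (k - 1) * EMS)` where `BMS` is the
#' between-target mean square and `EMS` the residual mean square of the
#' two-way (target x rater) decomposition. The confidence interval uses the
#' exact F bounds: with `F = BMS / EMS`,
#' `FL = F / qf(1 - alpha/2; n-1, (n-1)(k-1))` and
#' `FU = F * qf(1 - alpha/2; (n-1)(k-1), n-1)`, mapped through
#' `(x - 1) / (x + k - 1)`. The p-value tests ICC = 0 via
#' `F ~ F(n-1, (n-1)(k-1))`. Being a consistency ICC, the estimate is
#' invariant to adding a constant to any rater's column.
#'
#' @param m Numeric matrix, `n >= 2` targets in rows, `k >= 2` raters in
#'   columns, complete (no missing cells).
#' @param alpha Significance level (default 0.05, two-sided bounds).
#' @return A `test_result` with the ICC estimate, CI, F statistic, df pair
#'   and p-value.
#' @export
icc31 <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("ratings matrix must be complete and finite")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 targets and 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  if (bms <= 0 && ems <= 0) {
    stop("ICC undefined: no between-target and no residual variance")
  }
  if (ems <= 0) {
    # perfect consistency: residual exactly zero
    return(test_result(1, 1, 1, Inf, c(n - 1, (n - 1) * (k - 1)), 0, alpha))
  }
  fstat <- bms / ems
  est <- (bms - ems) / (bms + (k - 1) * ems)
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  fl <- fstat / stats::qf(1 - alpha / 2, df1, df2)
  fu <- fstat * stats::qf(1 - alpha / 2, df2, df1)
  test_result(est,
              (fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1),
              fstat, c(df1, df2),
              stats::pf(fstat, df1, df2, lower.tail = FALSE),
              alpha)
}

#' Summarize a SUS study
#'
#' Scores every respondent, then runs the benchmark t-test per scale
#' (overall, usability, learnability), mirroring the columns of a usability
#' results table: scale, n, mean, sd, CI bounds, t, df, p.
#'
#' @param responses List of [sus_response()] objects, `length >= 2`.
#' @param benchmark Null mean (default 68).
#' @param alpha Significance level.
#' @param round_ci When `TRUE`, adds `ci_low_disp`/`ci_high_disp` columns
#'   with the nearest-integer display rounding used in printed tables.
#' @return Data frame with one row per scale.
#' @export
summarize_study <- function(responses, benchmark = 68, alpha = 0.05,
                            round_ci = FALSE) {
  if (length(responses) < 2L) stop("need at least 2 respondents")
  scored <- lapply(responses, score_sus)
  scales <- c("overall", "usability", "learnability")
  rows <- lapply(scales, function(sc) {
    x <- vapply(scored, `[[`, numeric(1), sc)
    tr <- benchmark_ttest(x, benchmark = benchmark, alpha = alpha)
    data.frame(scale = sc, n = length(x), mean = mean(x), sd = stats::sd(x),
               ci_low = tr$ci_low, ci_high = tr$ci_high,
               t = tr$statistic, df = tr$df, p = tr$p_value)
  })
  out <- do.call(rbind, rows)
  if (round_ci) {
    out$ci_low_disp <- round(out$ci_low)
    out$ci_high_disp <- round(out$ci_high)
  }
  out
}
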