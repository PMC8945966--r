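test_that("pearson_r matches hand-computed values and flags degeneracy", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, x), 1.0)
  expect_equal(pearson_r(-x + 10, x), -1.0)
  # printed pairs (1,2), (2,4), (3,5): r = 1.5 / (1 * sqrt(7/3))
  expect_equal(pearson_r(c(2, 4, 5), c(1, 2, 3)), 1.5 / sqrt(7 / 3),
               tolerance = 1e-12)
  expect_equal(round(pearson_r(c(2, 4, 5), c(1, 2, 3)), 5), 0.98198)
  expect_error(pearson_r(c(1, 1, 1), x), "zero-variance")
  expect_error(pearson_r(1:4, 1:5), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("error_stats implements ME / sample SD / MAE", {
  ref <- c(100, 110, 120, 130)
  es <- error_stats(ref, ref)
  expect_equal(unlist(es), c(me = 0, sd = 0, mae = 0))
  es2 <- error_stats(ref + 5, ref)
  expect_equal(unlist(es2), c(me = 5, sd = 0, mae = 5))
  es3 <- error_stats(c(97, 113), c(100, 110))  # errors -3, +3
  expect_equal(es3$me, 0)
  expect_equal(es3$mae, 3)
  expect_equal(es3$sd, sqrt(18))  # 4.2426..., n-1 convention
  expect_error(error_stats(1:3, 1:4), "equal length")
})

test_that("aami_check applies inclusive thresholds", {
  expect_true(aami_check(0, 0))
  expect_false(aami_check(5.1, 4))
  expect_true(aami_check(-5.0, 8.0))  # closed boundary
  expect_false(aami_check(0, 8.01))
  expect_true(aami_check(9, 4, thresholds = c(10, 8)))
})

test_that("bhs_grade counts cumulative percentages and assigns letters", {
  g0 <- bhs_grade(rep(0, 10))
  expect_equal(unname(g0$percentages), c(100, 100, 100))
  expect_equal(g0$grade, "A")
  e <- c(4, 4, 4, 9, 9, 14, 14, 20, 20, 20)
  g <- bhs_grade(e)
  expect_equal(unname(g$percentages), c(30, 50, 70))
  expect_equal(g$grade, "D")
  # boundary: exactly the A row
  eA <- c(rep(4, 60), rep(9, 25), rep(14, 10), rep(99, 5))
  expect_equal(bhs_grade(eA)$grade, "A")
  expect_error(bhs_grade(numeric(0)), "empty")
})

test_that("metric implementations agree with brute-force recomputation", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    est <- rnorm(n, 120, 12)
    ref <- est + rnorm(n, sample(c(-4, 0, 4), 1), runif(1, 0.5, 9))
    e <- est - ref
    es <- error_stats(est, ref)
    expect_equal(es$me, sum(e) / n)
    expect_equal(es$mae, sum(abs(e)) / n)
    expect_equal(es$sd, sqrt(sum((e - mean(e))^2) / (n - 1)))
    if (stats::sd(est) > 0 && stats::sd(ref) > 0) {
      r_bf <- sum((est - mean(est)) * (ref - mean(ref))) /
        sqrt(sum((est - mean(est))^2) * sum((ref - mean(ref))^2))
      expect_equal(pearson_r(est, ref), r_bf)
    }
    # brute-force BHS re-count
    pct_bf <- c(sum(abs(e) <= 5), sum(abs(e) <= 10), sum(abs(e) <= 15)) / n * 100
    g <- bhs_grade(e)
    expect_equal(unname(g$percentages), pct_bf)
    grade_bf <- if (all(pct_bf >= c(60, 85, 95))) "A"
      else if (all(pct_bf >= c(50, 75, 90))) "B"
      else if (all(pct_bf >= c(40, 65, 85))) "C" else "D"
    expect_equal(g$grade, grade_bf)
    expect_equal(aami_check(es$me, es$sd),
                 abs(es$me) <= 5 && es$sd <= 8)
  }
})

test_that("shrinking all errors toward zero never lowers the BHS grade", {
  set.seed(12)
  rank <- c(A = 1, B = 2, C = 3, D = 4)
  for (i in 1:40) {
    e <- rnorm(sample(10:50, 1), 0, runif(1, 2, 15))
    g_full <- rank[bhs_grade(e)$grade]
    for (lambda in c(0.75, 0.5, 0.2, 0)) {
      g_shrunk <- rank[bhs_grade(e * lambda)$grade]
      expect_lte(g_shrunk, g_full)
    }
    # and percentages are nondecreasing across the bands
    pct <- bhs_grade(e)$percentages
    expect_true(all(diff(pct) >= 0))
  }
})

test_that("bland_altman reports bias and 1.96-SD limits", {
  ref <- c(100, 110, 120)
  ba0 <- bland_altman(ref, ref)
  expect_equal(unlist(ba0), c(bias = 0, lower = 0, upper = 0))
  ba5 <- bland_altman(ref + 5, ref)
  expect_equal(unlist(ba5), c(bias = 5, lower = 5, upper = 5))
  ba <- bland_altman(c(98, 112), c(100, 110))  # differences -2, +2
  expect_equal(ba$bias, 0)
  expect_equal(ba$upper, 1.96 * sqrt(8))
  expect_equal(ba$lower, -1.96 * sqrt(8))
})

test_that("the oracle estimator achieves the best possible report", {
  set.seed(5)
  sbp <- rnorm(50, 120, 10)
  dbp <- rnorm(50, 80, 7)
  rep_ <- evaluate_pairs(sbp, sbp, dbp, dbp)
  for (ch in c("sbp", "dbp")) {
    s <- rep_[[ch]]
    expect_equal(s$pearson_r, 1.0)
    expect_equal(s$mae, 0)
    expect_true(s$aami_pass)
    expect_equal(s$bhs$grade, "A")
    expect_equal(unname(s$bhs$percentages), c(100, 100, 100))
  }
})

test_that("a constant estimator is flagged degenerate, not given r = 0", {
  set.seed(6)
  ref <- rnorm(30, 120, 8)
  rep_ <- evaluate_pairs(rep(mean(ref), 30), ref, rep(80, 30), ref - 40)
  expect_true(rep_$sbp$degenerate)
  expect_true(is.na(rep_$sbp$pearson_r))
  # error statistics are still reported
  expect_true(is.finite(rep_$sbp$mae))
})

test_that("evaluation reports serialize deterministically", {
  set.seed(8)
  sbp <- rnorm(40, 120, 9)
  rep_ <- evaluate_pairs(sbp + rnorm(40), sbp, sbp - 40 + rnorm(40), sbp - 40)
  p1 <- file.path(tempdir(), "r1.json")
  p2 <- file.path(tempdir(), "r2.json")
  write_eval_report(rep_, p1)
  write_eval_report(rep_, p2)
  expect_identical(readLines(p1), readLines(p2))
  parsed <- jsonlite::read_json(p1, simplifyVector = TRUE)
  expect_equal(parsed$n, 40)
  expect_equal(parsed$sbp$mae, rep_$sbp$mae, tolerance = 1e-12)
})
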