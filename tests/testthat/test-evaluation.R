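test_that("chi-square matches direct summation and the stats oracle", {
  set.seed(71)
  m <- matrix(sample(20:120, 12), nrow = 3)
  res <- chi_square_test(m)
  # direct summation over cells
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(res$statistic, sum((m - expected)^2 / expected))
  expect_equal(res$df, 6)
  # stats::chisq.test without continuity correction
  oracle <- suppressWarnings(chisq.test(m, correct = FALSE))
  expect_equal(res$statistic, unname(oracle$statistic))
  expect_equal(res$p_value, oracle$p.value)
  expect_equal(res$cramers_v,
               sqrt(res$statistic / (sum(m) * (min(dim(m)) - 1))))
})

test_that("chi-square guards degenerate and sparse tables", {
  expect_error(chi_square_test(matrix(c(0, 0, 5, 7), 2)), "margin is zero")
  expect_error(chi_square_test(matrix(c(-1, 3, 4, 5), 2)), "nonnegative")
  expect_error(chi_square_test(matrix(c(1, 1, 1, 200), 2)), "below 1")
  expect_warning(chi_square_test(matrix(c(2, 50, 8, 60), 2)), "below 5")
  # independent margins give statistic exactly 0
  indep <- outer(c(10, 30), c(20, 80)) / 40
  expect_equal(suppressWarnings(chi_square_test(indep))$statistic, 0)
})

test_that("trend test agrees with stats::prop.trend.test and the 2x2 case", {
  succ <- c(30, 45, 60); tot <- c(100, 100, 100)
  res <- trend_test(succ, tot)
  oracle <- suppressWarnings(prop.trend.test(succ, tot))
  expect_equal(res$statistic^2, unname(oracle$statistic))
  expect_equal(res$p_value, oracle$p.value)
  expect_gt(res$statistic, 0)  # signed toward the increasing trend
  expect_lt(trend_test(rev(succ), tot)$statistic, 0)
  # flat proportions give Z = 0
  expect_equal(trend_test(c(20, 20, 20), tot)$statistic, 0)
  # two groups: Z^2 equals the Pearson chi-square of the 2x2 table
  res2 <- trend_test(c(30, 60), c(100, 100))
  tab <- rbind(c(30, 70), c(60, 40))
  expect_equal(res2$statistic^2, chi_square_test(tab)$statistic)
  expect_error(trend_test(c(1, 2), c(3, 4, 5)), "equal length")
  expect_error(trend_test(c(5, 6), c(4, 10)), "totals")
})

test_that("risk ratio reproduces hand values and shrinks with n", {
  # completion 64.6% of 61624 vs 78.0% of 96052 -> RR 1.21 (2 dp)
  rr <- risk_ratio(round(0.646 * 61624), 61624, round(0.78 * 96052), 96052)
  expect_equal(round(rr$rr, 2), 1.21)
  expect_lt(rr$ci_low, rr$rr)
  expect_gt(rr$ci_high, rr$rr)
  # identical groups give RR exactly 1
  expect_equal(risk_ratio(50, 100, 50, 100)$rr, 1)
  # quadrupling both samples narrows the interval
  narrow <- risk_ratio(200, 400, 240, 400)
  wide <- risk_ratio(50, 100, 60, 100)
  expect_lt(narrow$ci_high - narrow$ci_low, wide$ci_high - wide$ci_low)
  expect_error(risk_ratio(0, 100, 5, 100), "continuity correction")
})

test_that("Cohen's d matches the pooled-variance formula by hand", {
  x <- c(1, 2, 3, 4, 5); y <- c(3, 4, 5, 6, 7)
  sp <- sqrt((4 * var(x) + 4 * var(y)) / 8)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp)
  expect_equal(cohens_d(y, x), -cohens_d(x, y))
  # unit-variance samples a shift of exactly 1 apart
  z <- rnorm(5000)
  z <- (z - mean(z)) / sd(z)
  expect_equal(cohens_d(z + 1, z), 1)
  expect_error(cohens_d(1, c(2, 3)), ">= 2")
  expect_error(cohens_d(rep(2, 5), rep(2, 5)), "zero")
})

test_that("bootstrap interval behaves on degenerate and normal samples", {
  # a constant sample has a width-zero interval at the constant
  res <- bootstrap_ci(rep(3.5, 20), mean, B = 100, seed = 2)
  expect_equal(res$estimate, 3.5)
  expect_equal(res$ci_low, 3.5)
  expect_equal(res$ci_high, 3.5)
  # determinism under a fixed seed
  set.seed(99)
  x <- rnorm(80, mean = 2)
  a <- bootstrap_ci(x, mean, B = 300, seed = 7)
  expect_equal(a, bootstrap_ci(x, mean, B = 300, seed = 7))
  expect_lt(a$ci_low, a$estimate)
  expect_gt(a$ci_high, a$estimate)
  # data-frame records resample rows
  df <- data.frame(v = x)
  b <- bootstrap_ci(df, function(d) mean(d$v), B = 300, seed = 7)
  expect_equal(b$estimate, a$estimate)
  expect_error(bootstrap_ci(x, mean, B = 0), "B")
})

test_that("ITS recovers exact coefficients from noiseless series", {
  # noiseless series trip lm's "essentially perfect fit" warning; the point
  # estimates are still exact
  # flat series: all changes are exactly zero
  flat <- data.frame(time = 1:24, value = rep(0.6, 24))
  td <- suppressWarnings(tidy(its_fit(flat, 13)))
  expect_equal(td$estimate, c(0.6, 0, 0, 0))
  # pure level jump of +0.134 at the intervention
  jump <- data.frame(time = 1:24, value = 0.6 + 0.134 * (1:24 >= 13))
  tj <- suppressWarnings(tidy(its_fit(jump, 13)))
  expect_equal(tj$estimate[tj$term == "level_change"], 0.134)
  expect_equal(tj$estimate[tj$term == "slope_change"], 0)
  # slope change only
  slope <- data.frame(time = 1:24,
                      value = 0.5 + 0.01 * (1:24) +
                        0.02 * pmax(1:24 - 13, 0))
  ts <- suppressWarnings(tidy(its_fit(slope, 13)))
  expect_equal(ts$estimate[ts$term == "baseline_slope"], 0.01)
  expect_equal(ts$estimate[ts$term == "slope_change"], 0.02)
})

test_that("ITS recovers injected effects from noisy series", {
  set.seed(15)
  t <- 1:48
  y <- 0.55 + 0.002 * t + 0.10 * (t >= 25) + rnorm(48, sd = 0.01)
  td <- tidy(its_fit(data.frame(time = t, value = y), 25))
  lvl <- td[td$term == "level_change", ]
  expect_lt(abs(lvl$estimate - 0.10), 3 * lvl$std_error)
  expect_lt(lvl$p_value, 0.001)
})

test_that("ITS matches lm and its DW statistic matches lmtest", {
  set.seed(16)
  d <- data.frame(time = 1:30, value = rnorm(30, 0.6, 0.05))
  f <- its_fit(d, 16)
  ref <- lm(value ~ time + post + time_post,
            data = transform(d, post = as.numeric(time >= 16),
                             time_post = (time - 16) * (time >= 16)))
  expect_equal(tidy(f)$estimate, unname(coef(ref)))
  dw_oracle <- lmtest::dwtest(ref)
  expect_equal(glance(f)$durbin_watson, unname(dw_oracle$statistic))
  expect_s3_class(autoplot(f), "ggplot")
  expect_error(its_fit(d[1:4, ], 3), "3 points")
})
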