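#' Pearson chi-square test with Cramér's V
#'
#' Pearson's statistic without continuity correction,
#' \eqn{\chi^2 = \sum (O - E)^2 / E} with `df = (r-1)(k-1)`, plus the effect
#' size \eqn{V = \sqrt{\chi^2 / (n\,(\min(r,k)-1))}}.
#'
#' @param table nonnegative integer matrix of counts (r x k).
#' @return one-row tibble: `statistic`, `df`, `p_value`, `cramers_v`, `n`.
#' @examples
#' chi_square_test(matrix(c(30, 70, 60, 40), nrow = 2))
#' @export
chi_square_test <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0)) abort("counts must be nonnegative")
  n <- sum(m)
  if (n <= 0) abort("table total must be positive")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    abort("degenerate table: a row or column margin is zero")
  }
  expected <- outer(rs, cs) / n
  if (any(expected < 1)) abort("an expected cell count is below 1")
  if (any(expected < 5)) warn("an expected cell count is below 5")
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  v <- sqrt(stat / (n * (min(dim(m)) - 1)))
  tibble(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE),
         cramers_v = v, n = n)
}

#' Cochran–Armitage linear-by-linear trend test
#'
#' Tests for a linear trend in proportions across ordered groups. The Z
#' statistic is signed in the direction of the trend; with two groups its
#' square equals the Pearson chi-square of the 2x2 table.
#'
#' @param successes integer vector of event counts per group.
#' @param totals integer vector of group sizes.
#' @param scores numeric group scores (default equally spaced `1..k`).
#' @return one-row tibble: `statistic` (Z), `p_value` (two-sided).
#' @export
trend_test <- function(successes, totals, scores = seq_along(successes)) {
  if (length(successes) != length(totals) ||
      length(scores) != length(successes)) {
    abort("`successes`, `totals` and `scores` must have equal length")
  }
  if (length(successes) < 2) abort("need at least 2 groups")
  if (any(totals < successes)) abort("`totals` must be >= `successes`")
  N <- sum(totals)
  pbar <- sum(successes) / N
  num <- sum(scores * (successes - totals * pbar))
  v <- pbar * (1 - pbar) *
    (sum(totals * scores^2) - sum(totals * scores)^2 / N)
  if (v <= 0) abort("zero variance: all outcomes identical")
  z <- num / sqrt(v)
  tibble(statistic = z, p_value = 2 * pnorm(-abs(z)))
}

#' Relative risk with a Katz log-Wald confidence interval
#'
#' `rr = (events2/n2) / (events1/n1)`, CI
#' \eqn{\exp(\log rr \pm z \sqrt{(1-p_1)/(n_1 p_1) + (1-p_2)/(n_2 p_2)})}.
#' Group 1 is the reference (e.g. pre-intervention).
#'
#' @param events1,n1 reference-group events and size.
#' @param events2,n2 comparison-group events and size.
#' @param level confidence level (default 0.95).
#' @return one-row tibble: `rr`, `ci_low`, `ci_high`, `level`, `method`.
#' @examples
#' risk_ratio(round(0.646 * 61624), 61624, round(0.78 * 96052), 96052)
#' @export
risk_ratio <- function(events1, n1, events2, n2, level = 0.95) {
  if (min(events1, events2) <= 0) {
    abort(paste("zero events in a cell; add a continuity correction",
                "(e.g. 0.5) to all counts before calling"))
  }
  if (events1 > n1 || events2 > n2) abort("events cannot exceed group size")
  p1 <- events1 / n1; p2 <- events2 / n2
  rr <- p2 / p1
  se <- sqrt((1 - p1) / (n1 * p1) + (1 - p2) / (n2 * p2))
  z <- qnorm(1 - (1 - level) / 2)
  tibble(rr = rr, ci_low = exp(log(rr) - z * se),
         ci_high = exp(log(rr) + z * se), level = level,
         method = "katz_log_wald")
}

#' Cohen's d with pooled variance
#'
#' @param x,y numeric samples (length >= 2 each).
#' @return standardized mean difference `(mean(x) - mean(y)) / s_pooled` with
#'   the (n-1) pooled-variance convention.
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("each sample needs >= 2 values")
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 == 0) abort("pooled SD is zero")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples records (rows of a data frame, or elements of a vector) with
#' replacement and returns the percentile interval of the statistic.
#'
#' @param records data frame or vector of resampling units.
#' @param statistic function of a resampled `records` returning a scalar.
#' @param B number of resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return one-row tibble: `estimate` (on the original data), `boot_mean`,
#'   `ci_low`, `ci_high`, `level`, `B`, `seed`.
#' @examples
#' bootstrap_ci(rnorm(50), mean, B = 200, seed = 1)
#' @export
bootstrap_ci <- function(records, statistic, B = 1000, level = 0.95,
                         seed = 1) {
  if (B < 1) abort("`B` must be >= 1")
  n <- if (is.data.frame(records)) nrow(records) else length(records)
  if (n < 2) abort("need at least 2 records to resample")
  set.seed(seed)
  take <- if (is.data.frame(records)) {
    function(idx) records[idx, , drop = FALSE]
  } else {
    function(idx) records[idx]
  }
  boot <- vapply(seq_len(B), function(b) {
    statistic(take(sample.int(n, n, replace = TRUE)))
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- quantile(boot, probs = c(alpha, 1 - alpha), names = FALSE)
  tibble(estimate = statistic(records), boot_mean = mean(boot),
         ci_low = ci[1], ci_high = ci[2], level = level, B = B, seed = seed)
}

#' Interrupted time-series (segmented regression) fit
#'
#' Fits \eqn{Y_t = \beta_0 + \beta_1 t + \beta_2 \mathrm{post}_t +
#' \beta_3 (t - t_0)\,\mathrm{post}_t + \epsilon_t} by ordinary least
#' squares: \eqn{\beta_2} is the level change at the intervention and
#' \eqn{\beta_3} the slope change. The Durbin–Watson statistic of the
#' residuals is reported as an autocorrelation diagnostic.
#'
#' @param data data frame with numeric columns `time` and `value`, one row
#'   per period (e.g. monthly completion rates).
#' @param intervention_time time of the intervention; periods with
#'   `time >= intervention_time` are post.
#' @return an object of class `its_fit` wrapping the `lm` fit; see
#'   [tidy.its_fit()] and [glance.its_fit()].
#' @examples
#' d <- data.frame(time = 1:24, value = 0.6 + 0.1 * (1:24 >= 13))
#' tidy(its_fit(d, 13))
#' @export
its_fit <- function(data, intervention_time) {
  if (!all(c("time", "value") %in% names(data))) {
    abort("`data` must have columns 'time' and 'value'")
  }
  post <- as.numeric(data$time >= intervention_time)
  if (sum(post == 0) < 3 || sum(post == 1) < 3) {
    abort("need at least 3 points on each side of the intervention")
  }
  df <- data.frame(value = data$value, time = data$time, post = post,
                   time_post = (data$time - intervention_time) * post)
  fit <- lm(value ~ time + post + time_post, data = df)
  e <- stats::residuals(fit)
  dw <- sum(diff(e)^2) / sum(e^2)
  structure(list(fit = fit, dw = dw, intervention_time = intervention_time,
                 data = df), class = "its_fit")
}

#' @export
print.its_fit <- function(x, ...) {
  cat("<its_fit> segmented regression\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy ITS coefficients
#'
#' @param x an `its_fit` object.
#' @param ... unused.
#' @return tibble with `term` (`baseline_level`, `baseline_slope`,
#'   `level_change`, `slope_change`), `estimate`, `std_error`, `p_value`.
#' @method tidy its_fit
#' @export
tidy.its_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("baseline_level", "baseline_slope", "level_change",
                  "slope_change"),
         estimate = unname(s[, 1]), std_error = unname(s[, 2]),
         p_value = unname(s[, 4]))
}

#' One-row ITS summary
#'
#' @param x an `its_fit` object.
#' @param ... unused.
#' @return tibble with `r_squared`, `durbin_watson`, `n_pre`, `n_post`.
#' @method glance its_fit
#' @export
glance.its_fit <- function(x, ...) {
  tibble(r_squared = summary(x$fit)$r.squared, durbin_watson = x$dw,
         n_pre = sum(x$data$post == 0), n_post = sum(x$data$post == 1))
}

#' Plot an interrupted time-series fit
#'
#' @param object an `its_fit` object.
#' @param ... unused.
#' @return a ggplot object with observed points, the segmented fit and the
#'   intervention time.
#' @method autoplot its_fit
#' @export
autoplot.its_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- stats::fitted(object$fit)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted, group = .data$post),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$intervention_time, linetype = 2) +
    ggplot2::labs(x = "time", y = "outcome rate",
                  title = "Interrupted time series: level and slope change") +
    ggplot2::theme_minimal()
}
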