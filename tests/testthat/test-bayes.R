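# Build a scalper_bayes object with hand-chosen Gaussian parameters by
# fitting on a throwaway sample and overwriting the class parameters.
hand_fit <- function(mu_s, mu_l = rep(0, 13), sigma = diag(13),
                     prior = 0.05, threshold = 0.75) {
  fit <- scalper_bayes(make_gauss_dm(30, 30, mu_pos = 3, seed = 99),
                       prior = prior, threshold = threshold)
  fit$mu_scalper <- rep(mu_s, length.out = 13)
  fit$mu_legit <- rep(mu_l, length.out = 13)
  fit$sigma_scalper <- sigma
  fit$sigma_legit <- sigma
  fit
}

test_that("posterior equals the prior when class likelihoods are equal", {
  fit <- hand_fit(mu_s = 0)
  set.seed(4)
  X <- matrix(rnorm(5 * 13), 5, 13)
  expect_equal(posterior_scalper(fit, X), rep(0.05, 5))
  expect_equal(posterior_scalper(fit, X, prior = 0.3), rep(0.3, 5))
})

test_that("a likelihood ratio of 57 at prior 0.05 gives posterior 0.75", {
  # classes N(e1, I) vs N(0, I): log LR = x1 - 1/2, so x1 = log(57) + 1/2
  fit <- hand_fit(mu_s = c(1, rep(0, 12)))
  x <- c(log(57) + 0.5, rep(0, 12))
  expect_equal(posterior_scalper(fit, x), 0.75)
  # 0.05 * 57 / (0.05 * 57 + 0.95) worked by hand
  expect_equal(0.05 * 57 / (0.05 * 57 + 0.95), 0.75)
  # a point equidistant from both means has LR 1, posterior = prior
  mid <- c(0.5, rep(0, 12))
  expect_equal(posterior_scalper(fit, mid), 0.05)
})

test_that("flagging includes the threshold boundary", {
  fit <- hand_fit(mu_s = c(1, rep(0, 12)))
  dm <- make_gauss_dm(1, 1, mu_pos = 0, seed = 8)
  post <- posterior_scalper(fit, dm)
  fit$threshold <- post[1]  # decision boundary exactly at this account
  cls <- classify_accounts(fit, dm)
  expect_equal(cls$decision[1], "flag")
  expect_equal(cls$posterior, post)
  expect_equal(cls$effective_prior, rep(0.05, 2))
})

test_that("log-space posterior matches a direct density-ratio oracle", {
  dm <- make_gauss_dm(40, 160, mu_pos = 2, seed = 12)
  fit <- scalper_bayes(dm)
  X <- design_matrix_features(dm)
  ds <- mvtnorm::dmvnorm(X, fit$mu_scalper, fit$sigma_scalper)
  dl <- mvtnorm::dmvnorm(X, fit$mu_legit, fit$sigma_legit)
  oracle <- 0.05 * ds / (0.05 * ds + 0.95 * dl)
  expect_equal(posterior_scalper(fit, dm), oracle, tolerance = 1e-9)
})

test_that("fitted class means recover the generating means", {
  dm <- make_gauss_dm(400, 400, mu_pos = 1.5, seed = 5)
  fit <- scalper_bayes(dm)
  # 3 standard errors of a mean of 400 unit-variance draws = 0.15
  expect_true(all(abs(fit$mu_scalper - 1.5) < 0.15))
  expect_true(all(abs(fit$mu_legit - 0) < 0.15))
  # estimation error shrinks as the sample grows
  err <- function(n, seed) {
    f <- scalper_bayes(make_gauss_dm(n, n, mu_pos = 1.5, seed = seed))
    mean(abs(f$mu_scalper - 1.5))
  }
  expect_lt(err(1600, 7), err(100, 7))
})

test_that("full shrinkage produces a diagonal class covariance", {
  dm <- make_gauss_dm(50, 50, mu_pos = 1, seed = 3)
  fit <- scalper_bayes(dm, lambda_reg = 1)
  off <- fit$sigma_scalper - diag(diag(fit$sigma_scalper))
  expect_equal(max(abs(off)), 0)
  # refitting is deterministic
  expect_equal(fit, scalper_bayes(dm, lambda_reg = 1))
})

test_that("dynamic prior is neutral at 0.5 and monotone in congestion", {
  expect_equal(dynamic_prior(0.05, 0.5), 0.05)
  expect_equal(dynamic_prior(0.05, 1, gain = 2),
               plogis(qlogis(0.05) + 1))
  grid <- dynamic_prior(0.05, seq(0, 1, 0.1))
  expect_true(all(diff(grid) > 0))
  expect_gt(dynamic_prior(0.05, 0.9), 0.05)
  expect_lt(dynamic_prior(0.05, 0.1), 0.05)
  expect_error(dynamic_prior(0.05, 1.2), "congestion")
  expect_error(dynamic_prior(0, 0.5), "base_prior")
})

test_that("higher congestion never lowers the posterior", {
  fit <- hand_fit(mu_s = 1)
  set.seed(9)
  dm <- make_gauss_dm(10, 10, mu_pos = 0.5, seed = 9)
  lo <- classify_accounts(fit, dm, congestion = 0.2)$posterior
  hi <- classify_accounts(fit, dm, congestion = 0.9)$posterior
  expect_true(all(hi >= lo))
})

test_that("window update with the original batch reproduces the fit", {
  dm <- make_gauss_dm(40, 120, mu_pos = 2, seed = 21)
  fit <- scalper_bayes(dm)
  up <- sequential_update(fit, dm, mode = "window", window = 1)
  expect_equal(up$mu_scalper, fit$mu_scalper)
  expect_equal(up$sigma_scalper, fit$sigma_scalper)
  expect_equal(up$mu_legit, fit$mu_legit)
})

test_that("conjugate update with infinite pseudo-counts freezes parameters", {
  dm <- make_gauss_dm(40, 120, mu_pos = 2, seed = 22)
  fit <- scalper_bayes(dm)
  batch <- make_gauss_dm(30, 30, mu_pos = 5, seed = 23)
  frozen <- sequential_update(fit, batch, mode = "conjugate",
                              kappa0 = Inf, nu0 = Inf)
  expect_equal(frozen$mu_scalper, fit$mu_scalper)
  expect_equal(frozen$sigma_legit, fit$sigma_legit)
  # finite pseudo-counts pull the mean toward the batch mean
  moved <- sequential_update(fit, batch, mode = "conjugate",
                             kappa0 = 10, nu0 = 20)
  expect_gt(mean(moved$mu_scalper), mean(fit$mu_scalper))
})

test_that("window updates track behavioural drift that a frozen model misses", {
  train <- make_gauss_dm(60, 240, mu_pos = 8, seed = 31)
  fit <- scalper_bayes(train)
  # abnormal behaviour drifts from mean 8 to mean 1.5 per coordinate
  drifted <- make_gauss_dm(60, 240, mu_pos = 1.5, seed = 32)
  is_ab <- drifted$label == "abnormal"
  frozen_rate <- mean(
    classify_accounts(fit, drifted)$decision[is_ab] == "flag")
  updated <- sequential_update(fit, drifted, mode = "window", window = 1)
  updated_rate <- mean(
    classify_accounts(updated, drifted)$decision[is_ab] == "flag")
  expect_lt(frozen_rate, 0.5)
  expect_gte(updated_rate, 0.9)
})

test_that("fit guards reject unusable inputs", {
  small <- make_gauss_dm(5, 100, mu_pos = 2, seed = 1)
  expect_error(scalper_bayes(small), "at least",
               class = "scalpguard_fit_error")
  dm <- make_gauss_dm(30, 30, mu_pos = 2, seed = 2)
  expect_error(scalper_bayes(dm, prior = 1.2), "prior")
  expect_error(scalper_bayes(dm, threshold = 0), "threshold")
  fit <- scalper_bayes(dm)
  expect_error(posterior_scalper(fit, matrix(0, 2, 5)), "dimension mismatch")
  expect_error(posterior_scalper(fit, matrix(0, 1, 13), prior = 0), "prior")
})

test_that("threshold sweep reports a monotone flag rate", {
  dm <- make_gauss_dm(40, 160, mu_pos = 2, seed = 41)
  fit <- scalper_bayes(dm)
  sweep <- calibrate_threshold(fit, dm)
  expect_true(all(diff(sweep$flag_rate) <= 0))
  expect_true(all(sweep$sensitivity >= 0 & sweep$sensitivity <= 1,
                  na.rm = TRUE))
})

test_that("broom-style and plot methods keep their contracts", {
  dm <- make_gauss_dm(40, 160, mu_pos = 2, seed = 51)
  fit <- scalper_bayes(dm)
  td <- tidy(fit)
  expect_equal(td$feature, feature_names())
  expect_equal(td$separation, td$mean_abnormal - td$mean_normal)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$prior, 0.05)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "scalper_bayes")
})
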