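#' Fit the class-conditional Gaussian Bayes classifier
#'
#' The recognition engine: each class (abnormal scalper vs. normal patient)
#' gets a multivariate Gaussian fitted to its standardized behavioural
#' features, and accounts are scored by the posterior probability of the
#' abnormal class under a fixed prior. The prior is *not* estimated from the
#' training labels — it encodes the audited baseline prevalence of violative
#' accounts (default 5%) and is deliberately decoupled from sample prevalence.
#' Class covariances are shrunk toward their diagonal,
#' \eqn{\Sigma \leftarrow (1-\lambda)\Sigma + \lambda\,\mathrm{diag}(\Sigma)},
#' because the abnormal class is small and its full MLE covariance can be
#' near-singular.
#'
#' @param data a `design_matrix` from [build_design_matrix()] (or any tibble
#'   with the [feature_names()] columns and a `label` column).
#' @param prior fixed prior probability of the abnormal class (default 0.05).
#' @param threshold posterior decision threshold \eqn{\tau} (default 0.75);
#'   accounts with posterior `>= threshold` are flagged (boundary included).
#' @param lambda_reg diagonal shrinkage weight in `[0, 1]` (default 0.1).
#' @param ridge small ridge added to each class covariance diagonal (on the
#'   standardized scale, default 1e-4) so behaviours that are constant within
#'   a class (e.g. scalpers booking online only) keep a proper density.
#' @param positive label value of the abnormal class (default `"abnormal"`).
#' @return an object of class `scalper_bayes` with per-class means and
#'   covariances, the fixed prior and threshold, and the standardization
#'   parameters inherited from the design matrix.
#' @examples
#' cfg <- sim_config(n_accounts = 400, arrival_rate_per_day = 6, seed = 5)
#' ev <- simulate_events(simulate_cohort(cfg), cfg)
#' dm <- build_design_matrix(ev, label_accounts(ev))
#' fit <- scalper_bayes(dm)
#' glance(fit)
#' @export
scalper_bayes <- function(data, prior = 0.05, threshold = 0.75,
                          lambda_reg = 0.1, ridge = 1e-4,
                          positive = "abnormal") {
  if (prior <= 0 || prior >= 1) abort("`prior` must lie strictly in (0, 1)")
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must lie in (0, 1)")
  if (lambda_reg < 0 || lambda_reg > 1) abort("`lambda_reg` must lie in [0, 1]")
  feats <- feature_names()
  X <- as.matrix(as.data.frame(data)[, feats])
  y <- data$label
  d <- ncol(X)
  pos <- y == positive
  if (sum(pos) < d + 2 || sum(!pos) < d + 2) {
    abort(sprintf(
      "each class needs at least %d rows (got %d abnormal, %d normal)",
      d + 2, sum(pos), sum(!pos)), class = "scalpguard_fit_error")
  }
  fit_class <- function(Xc) {
    mu <- colMeans(Xc)
    S <- stats::cov(Xc)
    S <- (1 - lambda_reg) * S + lambda_reg * diag(diag(S), d) +
      ridge * diag(d)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      abort("class covariance singular after shrinkage; increase lambda_reg",
            class = "scalpguard_fit_error")
    }
    list(mu = mu, sigma = S)
  }
  ps <- fit_class(X[pos, , drop = FALSE])
  pl <- fit_class(X[!pos, , drop = FALSE])
  structure(list(
    prior = prior, threshold = threshold, lambda_reg = lambda_reg,
    ridge = ridge, positive = positive, features = feats,
    mu_scalper = ps$mu, sigma_scalper = ps$sigma,
    mu_legit = pl$mu, sigma_legit = pl$sigma,
    n_scalper = sum(pos), n_legit = sum(!pos),
    center = attr(data, "center"), scale = attr(data, "scale"),
    batches = list(list(X = X, y = y))),
    class = "scalper_bayes")
}

#' Posterior probability of the abnormal class
#'
#' Computes \eqn{P(\theta \mid X) = \pi g_s(X) / (\pi g_s(X) + (1-\pi)
#' g_l(X))} entirely in log space, where \eqn{g_s, g_l} are the class
#' Gaussian densities.
#'
#' @param fit a `scalper_bayes` object.
#' @param x numeric matrix (rows = accounts, standardized features), a single
#'   numeric vector, or a `design_matrix`.
#' @param prior optional prior override — a scalar or per-row vector (e.g.
#'   from [dynamic_prior()]); defaults to the fitted fixed prior.
#' @return numeric vector of posterior probabilities in (0, 1).
#' @export
posterior_scalper <- function(fit, x, prior = NULL) {
  stopifnot(inherits(fit, "scalper_bayes"))
  if (inherits(x, "design_matrix")) x <- design_matrix_features(x)
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(fit$mu_scalper)) {
    abort(sprintf("dimension mismatch: got %d features, model has %d",
                  ncol(x), length(fit$mu_scalper)))
  }
  p <- prior %||% fit$prior
  if (any(p <= 0 | p >= 1)) abort("prior must lie strictly in (0, 1)")
  ls <- dmvnorm_log(x, fit$mu_scalper, fit$sigma_scalper)
  ll <- dmvnorm_log(x, fit$mu_legit, fit$sigma_legit)
  a <- log(p) + ls
  b <- log(1 - p) + ll
  exp(a - logsumexp2(a, b))
}

#' Congestion-modulated dynamic prior
#'
#' Raises the model's vigilance when the clinic is congested: the prior is
#' shifted on the log-odds scale, `logit(prior') = logit(base_prior) +
#' gain * (congestion - 0.5)`, so congestion 0.5 is neutral and the output is
#' strictly increasing in congestion for positive gain.
#'
#' @param base_prior baseline prior in (0, 1).
#' @param congestion congestion index in `[0, 1]`, e.g. from
#'   [congestion_index()].
#' @param gain log-odds gain per unit congestion (default 2).
#' @return modulated prior in (0, 1).
#' @examples
#' dynamic_prior(0.05, congestion = 1, gain = 2)
#' @export
dynamic_prior <- function(base_prior, congestion, gain = 2) {
  if (any(congestion < 0 | congestion > 1)) {
    abort("`congestion` must lie in [0, 1]")
  }
  if (any(base_prior <= 0 | base_prior >= 1)) {
    abort("`base_prior` must lie strictly in (0, 1)")
  }
  plogis(qlogis(base_prior) + gain * (congestion - 0.5))
}

#' Score accounts and apply the decision threshold
#'
#' @param fit a `scalper_bayes` object.
#' @param data a `design_matrix` (standardized with the training parameters).
#' @param congestion optional congestion index in `[0, 1]`; when supplied the
#'   effective prior is [dynamic_prior()] of the fitted prior, otherwise the
#'   fixed prior is used.
#' @param gain log-odds gain passed to [dynamic_prior()].
#' @return tibble with `account_id`, `posterior`, `effective_prior`, and
#'   `decision` (`"flag"` iff `posterior >= threshold`, boundary included).
#' @export
classify_accounts <- function(fit, data, congestion = NULL, gain = 2) {
  p <- if (is.null(congestion)) fit$prior else
    dynamic_prior(fit$prior, congestion, gain)
  post <- posterior_scalper(fit, data, prior = p)
  tibble(account_id = data$account_id,
         posterior = post,
         effective_prior = p,
         decision = ifelse(post >= fit$threshold, "flag", "pass"))
}

#' @export
#' @rdname classify_accounts
#' @param object,newdata,... standard predict arguments; `newdata` is a
#'   `design_matrix`.
predict.scalper_bayes <- function(object, newdata, congestion = NULL,
                                  gain = 2, ...) {
  classify_accounts(object, newdata, congestion = congestion, gain = gain)
}

#' Sequentially update fitted parameters with a new batch
#'
#' The closed-loop feedback step: detection outcomes re-enter training.
#' `mode = "window"` refits on the most recent `window` batches (including the
#' new one); `mode = "conjugate"` performs a normal--inverse-Wishart update of
#' each class mean/covariance, with the current parameters as prior and
#' pseudo-counts `kappa0` (mean strength) and `nu0` (covariance strength).
#' Both modes leave the fixed prior and threshold untouched.
#'
#' @param fit a `scalper_bayes` object.
#' @param new_data a `design_matrix` batch (must be standardized with the
#'   training-time parameters).
#' @param mode `"window"` or `"conjugate"`.
#' @param window number of most recent batches retained in window mode.
#' @param kappa0,nu0 pseudo-counts for conjugate mode; default to the current
#'   per-class training counts. `Inf` freezes the parameters.
#' @return an updated `scalper_bayes` object.
#' @export
sequential_update <- function(fit, new_data, mode = c("window", "conjugate"),
                              window = 3, kappa0 = NULL, nu0 = NULL) {
  mode <- match.arg(mode)
  if (nrow(new_data) == 0) abort("new batch must be nonempty")
  feats <- fit$features
  Xn <- as.matrix(as.data.frame(new_data)[, feats])
  yn <- new_data$label

  if (mode == "window") {
    batches <- c(fit$batches, list(list(X = Xn, y = yn)))
    batches <- tail(batches, window)
    X <- do.call(rbind, lapply(batches, `[[`, "X"))
    y <- unlist(lapply(batches, `[[`, "y"))
    dm <- as_tibble(as.data.frame(X))
    names(dm) <- feats
    dm$label <- y
    dm$account_id <- sprintf("row%06d", seq_len(nrow(dm)))
    dm <- structure(dm, center = fit$center, scale = fit$scale,
                    class = c("design_matrix", class(dm)))
    out <- scalper_bayes(dm, prior = fit$prior, threshold = fit$threshold,
                         lambda_reg = fit$lambda_reg, ridge = fit$ridge,
                         positive = fit$positive)
    out$batches <- batches
    return(out)
  }

  # conjugate NIW update per class
  upd <- function(mu0, S0, Xc, k0, v0) {
    n <- nrow(Xc)
    if (n == 0) return(list(mu = mu0, sigma = S0))
    if (is.infinite(k0) || is.infinite(v0)) return(list(mu = mu0, sigma = S0))
    xbar <- colMeans(Xc)
    mu1 <- (k0 * mu0 + n * xbar) / (k0 + n)
    Sc <- crossprod(sweep(Xc, 2, xbar))
    dev <- xbar - mu0
    S1 <- (v0 * S0 + Sc + (k0 * n / (k0 + n)) * tcrossprod(dev)) / (v0 + n)
    list(mu = mu1, sigma = S1)
  }
  k0s <- kappa0 %||% fit$n_scalper; v0s <- nu0 %||% fit$n_scalper
  k0l <- kappa0 %||% fit$n_legit;   v0l <- nu0 %||% fit$n_legit
  pos <- yn == fit$positive
  us <- upd(fit$mu_scalper, fit$sigma_scalper, Xn[pos, , drop = FALSE],
            k0s, v0s)
  ul <- upd(fit$mu_legit, fit$sigma_legit, Xn[!pos, , drop = FALSE],
            k0l, v0l)
  fit$mu_scalper <- us$mu; fit$sigma_scalper <- us$sigma
  fit$mu_legit <- ul$mu;   fit$sigma_legit <- ul$sigma
  fit$n_scalper <- fit$n_scalper + sum(pos)
  fit$n_legit <- fit$n_legit + sum(!pos)
  fit
}

#' Sweep the decision threshold and report the trade-off
#'
#' Recreates the sensitivity--specificity trade-off analysis used to pick the
#' operating threshold: posteriors are computed on a held-out split and
#' sensitivity/specificity are reported over a grid of candidate thresholds.
#'
#' @param fit a `scalper_bayes` object.
#' @param data held-out `design_matrix` with labels.
#' @param grid numeric vector of candidate thresholds.
#' @return tibble with `threshold`, `sensitivity`, `specificity`, `precision`,
#'   `flag_rate`.
#' @export
calibrate_threshold <- function(fit, data,
                                grid = seq(0.05, 0.95, by = 0.05)) {
  post <- posterior_scalper(fit, data)
  truth <- data$label == fit$positive
  purrr::map_dfr(grid, function(tau) {
    pred <- post >= tau
    tibble(threshold = tau,
           sensitivity = if (any(truth)) mean(pred[truth]) else NA_real_,
           specificity = if (any(!truth)) mean(!pred[!truth]) else NA_real_,
           precision = if (any(pred)) mean(truth[pred]) else NA_real_,
           flag_rate = mean(pred))
  })
}

#' @export
print.scalper_bayes <- function(x, ...) {
  cat("<scalper_bayes> class-conditional Gaussian classifier\n")
  cat(sprintf("  features: %d; prior: %.3f (fixed); threshold: %.2f\n",
              length(x$features), x$prior, x$threshold))
  cat(sprintf("  training rows: %d abnormal / %d normal; shrinkage %.2f\n",
              x$n_scalper, x$n_legit, x$lambda_reg))
  invisible(x)
}

#' Tidy the fitted class means
#'
#' @param x a `scalper_bayes` object.
#' @param ... unused.
#' @return tibble with one row per feature: the standardized class means and
#'   their difference (abnormal minus normal), a direct readout of which
#'   behaviours drive the classifier.
#' @method tidy scalper_bayes
#' @export
tidy.scalper_bayes <- function(x, ...) {
  tibble(feature = x$features,
         mean_abnormal = unname(x$mu_scalper),
         mean_normal = unname(x$mu_legit),
         separation = unname(x$mu_scalper - x$mu_legit))
}

#' One-row model summary
#'
#' @param x a `scalper_bayes` object.
#' @param ... unused.
#' @return one-row tibble: dimensions, class counts, prior, threshold,
#'   shrinkage.
#' @method glance scalper_bayes
#' @export
glance.scalper_bayes <- function(x, ...) {
  tibble(n_features = length(x$features), n_abnormal = x$n_scalper,
         n_normal = x$n_legit, prior = x$prior, threshold = x$threshold,
         lambda_reg = x$lambda_reg)
}

#' Plot class separation of the fitted model
#'
#' Dot plot of standardized class means per feature, showing which behaviours
#' separate automated scalping from legitimate use.
#'
#' @param object a `scalper_bayes` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot scalper_bayes
#' @export
autoplot.scalper_bayes <- function(object, ...) {
  td <- tidy(object) |>
    tidyr::pivot_longer(c("mean_abnormal", "mean_normal"),
                        names_to = "class", values_to = "mean")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$mean, y = .data$feature,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "standardized class mean", y = NULL,
                  title = "Behavioural separation of account classes") +
    ggplot2::theme_minimal()
}
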