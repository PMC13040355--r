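#' Confusion-matrix metrics and rank-based AUC
#'
#' Standard binary classification metrics. When `scores` are supplied the AUC
#' is computed from the Mann–Whitney rank statistic (ties counted half),
#' i.e. the probability that a random positive outscores a random negative.
#'
#' @param labels binary truth vector (logical, 0/1, or the `positive` value).
#' @param predictions binary predictions on the same encoding.
#' @param scores optional numeric scores for AUC.
#' @param positive value of `labels`/`predictions` treated as positive
#'   (default `TRUE`; use e.g. `"abnormal"` for character labels).
#' @return one-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1`, `auc` (NA without scores).
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0), scores = c(.9, .6, .4, .1),
#'                   positive = 1)
#' @export
confusion_metrics <- function(labels, predictions, scores = NULL,
                              positive = TRUE) {
  if (length(labels) != length(predictions)) {
    abort("`labels` and `predictions` must have equal length")
  }
  truth <- labels == positive
  pred <- predictions == positive
  tp <- sum(truth & pred); fp <- sum(!truth & pred)
  fn <- sum(truth & !pred); tn <- sum(!truth & !pred)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  auc <- NA_real_
  if (!is.null(scores)) {
    if (all(truth) || all(!truth)) {
      abort("AUC undefined: labels contain a single class")
    }
    auc <- auc_rank(truth, scores)
  }
  tibble(accuracy = (tp + tn) / length(truth),
         sensitivity = rec,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         precision = prec, f1 = f1, auc = auc)
}

#' AUC from the Mann–Whitney rank statistic
#'
#' @param truth logical vector of positives.
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`; ties contribute 1/2.
#' @export
auc_rank <- function(truth, scores) {
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) abort("need both classes for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' F1 score from precision and recall
#'
#' @param precision,recall values in `[0, 1]`.
#' @return harmonic mean `2 P R / (P + R)`.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) abort("precision + recall must be positive")
  2 * precision * recall / (precision + recall)
}

#' Equal Opportunity fairness report
#'
#' Computes the true-positive rate (recall among truly abnormal accounts) for
#' each protected group and the maximum pairwise gap. Groups with no positive
#' labels cannot contribute a TPR and are excluded with a warning recorded in
#' the output.
#'
#' @param labels binary truth vector.
#' @param predictions binary predictions.
#' @param groups group membership vector (e.g. age band).
#' @param positive positive value of `labels`/`predictions`.
#' @return list of class `fairness_report`: `by_group` tibble (`group`,
#'   `n_positive`, `tpr`), `gap` (max − min TPR), `excluded` groups.
#' @export
equal_opportunity_gap <- function(labels, predictions, groups,
                                  positive = TRUE) {
  if (!(length(labels) == length(predictions) &&
        length(labels) == length(groups))) {
    abort("inputs must have equal length")
  }
  truth <- labels == positive
  pred <- predictions == positive
  d <- tibble(truth = truth, pred = pred, group = as.character(groups)) |>
    group_by(.data$group) |>
    summarise(n_positive = sum(.data$truth),
              tpr = ifelse(sum(.data$truth) > 0,
                           sum(.data$pred & .data$truth) / sum(.data$truth),
                           NA_real_))
  excluded <- d$group[d$n_positive == 0]
  if (length(excluded) > 0) {
    warn(paste("groups without positive labels excluded from TPR gap:",
               paste(excluded, collapse = ", ")))
  }
  used <- d[d$n_positive > 0, ]
  gap <- if (nrow(used) > 0) max(used$tpr) - min(used$tpr) else NA_real_
  structure(list(by_group = d, gap = gap, excluded = excluded),
            class = "fairness_report")
}

#' @export
print.fairness_report <- function(x, ...) {
  cat(sprintf("<fairness_report> max TPR gap: %.3f\n", x$gap))
  print(x$by_group)
  invisible(x)
}

#' Stratified cross-validation test-set assignments
#'
#' Builds the held-out index sets used by [cross_validate()]: stratified
#' k-fold (per-class round-robin after a random shuffle; `k = n` degenerates
#' to leave-one-out) or repeated stratified random splits.
#'
#' @param truth logical vector marking the positive class.
#' @param protocol `"kfold"` or `"split"`.
#' @param k number of folds.
#' @param repeats number of repeated splits.
#' @param train_frac training fraction for the split protocol.
#' @param seed integer seed.
#' @return list of integer vectors of test-set row indices.
#' @export
cv_folds <- function(truth, protocol = c("kfold", "split"), k = 10,
                     repeats = 10, train_frac = 0.7, seed = 1) {
  protocol <- match.arg(protocol)
  set.seed(seed)
  n <- length(truth)
  if (protocol == "kfold") {
    if (k > n) abort("k cannot exceed the number of rows")
    if (k == n) return(lapply(seq_len(n), identity))  # leave-one-out
    if (sum(truth) < k || sum(!truth) < k) {
      abort("class too small to stratify into k folds")
    }
    strat <- function(idx) {
      f <- integer(length(idx))
      f[sample(seq_along(idx))] <- rep_len(seq_len(k), length(idx))
      f
    }
    fold <- integer(n)
    fold[truth] <- strat(which(truth))
    fold[!truth] <- strat(which(!truth))
    lapply(seq_len(k), function(i) which(fold == i))
  } else {
    if (sum(truth) < 2 || sum(!truth) < 2) {
      abort("each class needs at least 2 rows to stratify")
    }
    lapply(seq_len(repeats), function(i) {
      sort(c(sample(which(truth), round(sum(truth) * (1 - train_frac))),
             sample(which(!truth), round(sum(!truth) * (1 - train_frac)))))
    })
  }
}

#' Cross-validate the Gaussian Bayes classifier
#'
#' Two protocols are offered: stratified k-fold (default k = 10) and repeated
#' random 70/30 splits; both keep each training split stratified so both
#' classes are always present.
#'
#' @param data a `design_matrix` with labels.
#' @param protocol `"kfold"` or `"split"`.
#' @param k number of folds (kfold protocol).
#' @param repeats number of repeated splits (split protocol).
#' @param train_frac training fraction for the split protocol (default 0.7).
#' @param seed integer seed controlling fold assignment.
#' @param prior,threshold,lambda_reg,ridge passed to [scalper_bayes()].
#' @param positive positive label value.
#' @return list of class `cv_result`: `folds` (per-fold [confusion_metrics()]
#'   rows), `summary` (mean metrics), `pooled_auc` (AUC over pooled held-out
#'   scores).
#' @export
cross_validate <- function(data, protocol = c("kfold", "split"), k = 10,
                           repeats = 10, train_frac = 0.7, seed = 1,
                           prior = 0.05, threshold = 0.75, lambda_reg = 0.1,
                           ridge = 1e-4, positive = "abnormal") {
  protocol <- match.arg(protocol)
  n <- nrow(data)
  truth <- data$label == positive
  assignments <- cv_folds(truth, protocol = protocol, k = k,
                          repeats = repeats, train_frac = train_frac,
                          seed = seed)

  sub_dm <- function(idx) {
    structure(data[idx, ], center = attr(data, "center"),
              scale = attr(data, "scale"),
              class = c("design_matrix", class(tibble())))
  }
  pooled_scores <- numeric(0); pooled_truth <- logical(0)
  folds <- purrr::imap_dfr(assignments, function(test_idx, i) {
    fit <- scalper_bayes(sub_dm(setdiff(seq_len(n), test_idx)), prior = prior,
                         threshold = threshold, lambda_reg = lambda_reg,
                         ridge = ridge, positive = positive)
    sc <- posterior_scalper(fit, sub_dm(test_idx))
    pooled_scores <<- c(pooled_scores, sc)
    pooled_truth <<- c(pooled_truth, truth[test_idx])
    cm <- confusion_metrics(truth[test_idx], sc >= threshold,
                            scores = if (length(unique(truth[test_idx])) == 2)
                              sc else NULL,
                            positive = TRUE)
    cm$fold <- i
    cm
  })
  summary <- folds |>
    summarise(dplyr::across(c("accuracy", "sensitivity", "specificity",
                              "precision", "f1", "auc"),
                            function(v) mean(v, na.rm = TRUE)))
  structure(list(folds = folds, summary = summary,
                 pooled_auc = auc_rank(pooled_truth, pooled_scores),
                 protocol = protocol, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d folds; pooled AUC %.3f\n",
              x$protocol, nrow(x$folds), x$pooled_auc))
  print(x$summary)
  invisible(x)
}
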