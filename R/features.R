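#' Names of the behavioural feature columns
#'
#' The model summarises each account's history into 12 behavioural variables.
#' Booking hour-of-day is circular and is expanded into a sin/cos pair, so the
#' design matrix carries 13 numeric columns for the 12 nominal variables.
#'
#' @return character vector of column names, in canonical order:
#'   `hour_sin`, `hour_cos` (circular mean booking hour), `dept_entropy`
#'   (department-choice entropy, nats), `bookings_per_day` (bookings per
#'   active day), `mean_interop_s` (mean inter-operation interval, s),
#'   `min_op_s` (fastest operation, s), `max_cancels_48h` (peak cancels in a
#'   48 h window), `cancel_ratio` (cancels / bookings), `max_card_fanout`
#'   (largest card fan-out over the account's devices), `n_ips` (distinct
#'   IPs), `mean_session_s` (mean session duration, s), `history_days`
#'   (span between first and last event, days), `online_share` (share of
#'   bookings made online).
#' @export
feature_names <- function() {
  c("hour_sin", "hour_cos", "dept_entropy", "bookings_per_day",
    "mean_interop_s", "min_op_s", "max_cancels_48h", "cancel_ratio",
    "max_card_fanout", "n_ips", "mean_session_s", "history_days",
    "online_share")
}

#' Extract behavioural features for every account in a log
#'
#' A pure function of the event multiset: permuting the log leaves the result
#' unchanged. Single-event degeneracies are resolved totally so the Gaussian
#' model never sees missing values: a lone operation yields
#' `mean_interop_s = interop_cap` and a one-event session contributes its own
#' `op_duration_s` as session duration.
#'
#' @param events event log tibble.
#' @param interop_cap value (seconds) used for `mean_interop_s` when an
#'   account has a single user-initiated operation (default 86400).
#' @return tibble with `account_id` plus the columns of [feature_names()].
#' @examples
#' cfg <- sim_config(n_accounts = 40, arrival_rate_per_day = 4, seed = 11)
#' fx <- extract_features_all(simulate_events(simulate_cohort(cfg), cfg))
#' @export
extract_features_all <- function(events, interop_cap = 86400) {
  if (nrow(events) == 0) abort("cannot extract features from an empty log")
  fan <- cards_per_device(events)
  fan_lookup <- setNames(fan$n_cards, fan$device_id)

  user <- events[events$action %in% c("book", "cancel"), ]
  tsec <- as.numeric(user$timestamp)

  sess <- user |>
    group_by(.data$account_id, .data$session_id) |>
    summarise(dur = if (n() == 1) .data$op_duration_s[1] else
      max(as.numeric(.data$timestamp)) - min(as.numeric(.data$timestamp)),
      .groups = "drop") |>
    group_by(.data$account_id) |>
    summarise(mean_session_s = mean(.data$dur))

  books <- user[user$action == "book", ]
  hod <- (as.numeric(books$timestamp) %% 86400) / 3600
  books$hsin <- sin(2 * pi * hod / 24)
  books$hcos <- cos(2 * pi * hod / 24)
  bk <- books |>
    group_by(.data$account_id) |>
    summarise(
      hour_sin = mean(.data$hsin),
      hour_cos = mean(.data$hcos),
      dept_entropy = entropy_nats(table(.data$department)),
      n_books = n(),
      active_days = n_distinct(as.Date(.data$timestamp)),
      online_share = mean(.data$channel == "online"))

  us <- user |>
    group_by(.data$account_id) |>
    summarise(
      mean_interop_s = if (n() == 1) interop_cap else
        mean(diff(sort(as.numeric(.data$timestamp)))),
      min_op_s = min(.data$op_duration_s),
      max_cancels_48h = max_events_in_window(
        as.numeric(.data$timestamp[.data$action == "cancel"]), 48 * 3600),
      n_cancels = sum(.data$action == "cancel"),
      n_ips = n_distinct(.data$ip),
      max_card_fanout = max(fan_lookup[unique(.data$device_id)]),
      history_days = (max(as.numeric(.data$timestamp)) -
                        min(as.numeric(.data$timestamp))) / 86400)

  out <- us |>
    left_join(bk, by = "account_id") |>
    left_join(sess, by = "account_id") |>
    mutate(
      n_books = dplyr::coalesce(.data$n_books, 0L),
      bookings_per_day = ifelse(.data$n_books > 0,
                                .data$n_books / pmax(.data$active_days, 1), 0),
      cancel_ratio = ifelse(.data$n_books > 0,
                            pmin(1, .data$n_cancels / .data$n_books), 0),
      hour_sin = dplyr::coalesce(.data$hour_sin, 0),
      hour_cos = dplyr::coalesce(.data$hour_cos, 0),
      dept_entropy = dplyr::coalesce(.data$dept_entropy, 0),
      online_share = dplyr::coalesce(.data$online_share, 0))
  out[, c("account_id", feature_names())]
}

#' Extract the feature vector of a single account
#'
#' @param events event log tibble.
#' @param account_id account to summarise; must have at least one event.
#' @param interop_cap see [extract_features_all()].
#' @return one-row tibble.
#' @export
extract_features <- function(events, account_id, interop_cap = 86400) {
  sub <- events[events$account_id == account_id, ]
  if (nrow(sub) == 0) {
    abort(sprintf("account '%s' has no events", account_id))
  }
  # fan-out is shared device state, so features come from the full log
  full <- extract_features_all(events, interop_cap = interop_cap)
  full[full$account_id == account_id, ]
}

#' Build a labeled, standardized design matrix
#'
#' Joins per-account features with ground-truth labels (and optional cohort
#' group attributes for fairness reporting), and standardizes each feature
#' column to mean 0 / SD 1. The standardization parameters are stored as
#' attributes so the identical transform can be replayed on scoring-time data.
#'
#' @param events event log tibble.
#' @param labels tibble from [label_accounts()]; must cover every account with
#'   events.
#' @param cohort optional cohort tibble contributing `age_band`, `socio_band`,
#'   `latent_class`.
#' @param standardize logical; apply/record z-scoring (default `TRUE`).
#' @param center,scale optional precomputed standardization vectors (named by
#'   feature) used to transform this matrix with training-time parameters.
#' @return a `design_matrix` tibble: `account_id`, `label`, optional group
#'   columns, and the feature columns; attributes `center` and `scale` hold
#'   the standardization parameters (constant columns get scale 1).
#' @export
build_design_matrix <- function(events, labels, cohort = NULL,
                                standardize = TRUE, center = NULL,
                                scale = NULL) {
  fx <- extract_features_all(events)
  missing <- setdiff(fx$account_id, labels$account_id)
  if (length(missing) > 0) {
    abort(sprintf("labels missing for %d account(s), e.g. %s",
                  length(missing), missing[1]))
  }
  out <- fx |>
    left_join(labels[, c("account_id", "label")], by = "account_id")
  if (!is.null(cohort)) {
    keep <- intersect(c("account_id", "latent_class", "age_band",
                        "socio_band"), names(cohort))
    out <- left_join(out, cohort[, keep], by = "account_id")
  }
  feats <- feature_names()
  if (standardize) {
    if (is.null(center)) {
      center <- vapply(out[feats], mean, numeric(1))
      s <- vapply(out[feats], sd, numeric(1))
      s[!is.finite(s) | s == 0] <- 1
      scale <- s
    }
    for (f in feats) out[[f]] <- (out[[f]] - center[f]) / scale[f]
  } else {
    center <- setNames(rep(0, length(feats)), feats)
    scale <- setNames(rep(1, length(feats)), feats)
  }
  structure(out, center = center, scale = scale,
            class = c("design_matrix", class(out)))
}

#' Numeric feature matrix of a design matrix
#' @param x a `design_matrix`.
#' @return numeric matrix (rows = accounts) of the feature columns.
#' @export
design_matrix_features <- function(x) {
  as.matrix(as.data.frame(x)[, feature_names()])
}
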