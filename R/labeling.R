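#' Maximum number of cancelations in any sliding window
#'
#' Counts an account's `cancel` events inside every window of width
#' `window_hours` anchored at a cancel event (closed on the left, open on the
#' right) and returns the maximum. Because the count as a function of the
#' window's left edge only changes at event times, anchoring at each cancel
#' enumerates all attainable values.
#'
#' @param events event log tibble.
#' @param account_id account to inspect; unknown accounts yield 0.
#' @param window_hours window width in hours (default 48).
#' @return nonnegative integer.
#' @examples
#' # 4 cancels spread over 47 hours all share one 48 h window
#' @export
max_cancels_in_window <- function(events, account_id, window_hours = 48) {
  t <- events$timestamp[events$account_id == account_id &
                          events$action == "cancel"]
  max_events_in_window(as.numeric(t), window_hours * 3600)
}

# Core sliding-window count on numeric times (seconds); window [t, t + w).
max_events_in_window <- function(t, w) {
  if (length(t) == 0) return(0L)
  t <- sort(t)
  # for each anchor i, count events with t_j in [t_i, t_i + w)
  upper <- findInterval(t + w - 1e-9, t)
  max(upper - seq_along(t) + 1L)
}

#' Distinct medical-card IDs per device
#'
#' @param events event log tibble.
#' @return tibble with `device_id` and `n_cards`, the number of distinct card
#'   IDs ever observed with that device over the whole log.
#' @export
cards_per_device <- function(events) {
  if (nrow(events) == 0) {
    return(tibble(device_id = character(), n_cards = integer()))
  }
  events |>
    distinct(.data$device_id, .data$card_id) |>
    count(.data$device_id, name = "n_cards")
}

#' Operation-speed threshold from the fast tail of manual operations
#'
#' The automation signature is an operation faster than all but the fastest
#' (100 - percentile)% of reference (manual) operations: for the default
#' `percentile = 99` this is the 1st percentile of the reference duration
#' distribution, i.e. the boundary of the fast 1% tail. A fixed override (the
#' documented 2 s default rule) can be supplied instead via `fixed`.
#'
#' @param events event log; reference durations are taken from user-initiated
#'   actions (`book`, `cancel`).
#' @param percentile reference percentile (default 99: fastest 1% tail).
#' @param fixed optional fixed threshold in seconds, returned unchanged.
#' @param reference_accounts optional character vector restricting the
#'   reference set (e.g. currently unflagged accounts).
#' @return threshold in seconds.
#' @export
speed_threshold <- function(events, percentile = 99, fixed = NULL,
                            reference_accounts = NULL) {
  if (!is.null(fixed)) return(fixed)
  ref <- events[events$action %in% c("book", "cancel"), ]
  if (!is.null(reference_accounts)) {
    ref <- ref[ref$account_id %in% reference_accounts, ]
  }
  d <- ref$op_duration_s
  if (length(d) == 0) abort("no reference operations to compute a speed threshold")
  unname(quantile(d, probs = 1 - percentile / 100, type = 7))
}

#' Ground-truth labeling of abnormal accounts
#'
#' Applies the two-of-three behavioural rule: an account is `abnormal` when at
#' least two of the following hold: (1) more than `max_cancels` cancelations in
#' some sliding window of `window_hours`; (2) one of its devices is associated
#' with more than `max_cards` distinct card IDs; (3) some operation is faster
#' than the speed threshold. A device-level fan-out flag marks every account
#' that used the device. `label_noise > 0` flips labels independently with
#' that probability, emulating residual error left after manual verification.
#'
#' @param events event log tibble.
#' @param window_hours sliding window width in hours (default 48).
#' @param max_cancels strict cancel threshold (default 3: flag on 4+).
#' @param max_cards strict card fan-out threshold (default 5: flag on 6+).
#' @param speed_fixed fixed speed threshold in seconds (default 2, the
#'   documented automation signature); set `NULL` to use `speed_percentile`.
#' @param speed_percentile percentile passed to [speed_threshold()] when no
#'   fixed threshold is given.
#' @param label_noise flip probability applied to final labels (default 0).
#' @param seed seed used only when `label_noise > 0`.
#' @param accounts optional character vector of account ids to label; ids
#'   without events get all-false flags and a `"normal"` label. Defaults to
#'   the accounts appearing in the log.
#' @return tibble with one row per account appearing in the log:
#'   `account_id`, logical flags `cancel_burst`, `card_fanout`, `fast_ops`,
#'   and `label` (`"abnormal"`/`"normal"`).
#' @examples
#' cfg <- sim_config(n_accounts = 100, arrival_rate_per_day = 8, seed = 3)
#' ev <- simulate_events(simulate_cohort(cfg), cfg)
#' table(label_accounts(ev)$label)
#' @export
label_accounts <- function(events, window_hours = 48, max_cancels = 3,
                           max_cards = 5, speed_fixed = 2,
                           speed_percentile = 99, label_noise = 0,
                           seed = NULL, accounts = NULL) {
  accounts <- accounts %||% sort(unique(events$account_id))
  if (length(accounts) == 0) {
    return(tibble(account_id = character(), cancel_burst = logical(),
                  card_fanout = logical(), fast_ops = logical(),
                  label = character()))
  }

  w <- window_hours * 3600
  burst <- events |>
    filter(.data$action == "cancel") |>
    group_by(.data$account_id) |>
    summarise(max_win = max_events_in_window(as.numeric(.data$timestamp), w))
  burst_flag <- setNames(burst$max_win > max_cancels, burst$account_id)

  fan <- cards_per_device(events)
  fan_devices <- fan$device_id[fan$n_cards > max_cards]
  fan_accounts <- unique(events$account_id[events$device_id %in% fan_devices])

  thr <- speed_threshold(events, percentile = speed_percentile,
                         fixed = speed_fixed)
  user_ops <- events[events$action %in% c("book", "cancel"), ]
  fast_accounts <- unique(user_ops$account_id[user_ops$op_duration_s < thr])

  out <- tibble(
    account_id = accounts,
    cancel_burst = unname(burst_flag[accounts]) %in% TRUE,
    card_fanout = accounts %in% fan_accounts,
    fast_ops = accounts %in% fast_accounts)
  out$label <- ifelse(out$cancel_burst + out$card_fanout + out$fast_ops >= 2,
                      "abnormal", "normal")
  if (label_noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    flip <- runif(nrow(out)) < label_noise
    out$label[flip] <- ifelse(out$label[flip] == "abnormal", "normal",
                              "abnormal")
  }
  out
}
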