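#' Simulate an account cohort
#'
#' Draws the latent population of actors behind a registration stream. Each
#' account is independently a scalper with probability
#' `config$scalper_fraction`; scalper accounts receive a single automation
#' device fanned out over 6+ medical-card IDs and a rotating IP pool, while
#' legitimate accounts carry one or two personal devices and cards.
#'
#' @param config a [sim_config()] object.
#' @param seed optional integer overriding `config$seed`.
#' @return a tibble with one row per account: `account_id`, `latent_class`
#'   (`"legitimate"`/`"scalper"`), demographic bands, and list-columns
#'   `device_ids`, `card_ids`, `ip_ids`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_accounts = 50, seed = 7))
#' @export
simulate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a sim_config object",
          class = "scalpguard_config_error")
  }
  set.seed(seed %||% config$seed)
  n <- config$n_accounts
  is_scalper <- runif(n) < config$scalper_fraction
  id <- sprintf("acct%05d", seq_len(n))

  draw_cards <- function(k) {
    s <- config$scalper_cards_per_device
    sample(s$support, k, replace = TRUE, prob = s$prob)
  }
  n_cards <- ifelse(is_scalper, draw_cards(n), sample(1:2, n, replace = TRUE,
                                                      prob = c(0.7, 0.3)))
  n_devices <- ifelse(is_scalper, 1L, sample(1:2, n, replace = TRUE,
                                             prob = c(0.8, 0.2)))
  n_ips <- ifelse(is_scalper, sample(3:8, n, replace = TRUE),
                  sample(1:3, n, replace = TRUE))

  tibble(
    account_id = id,
    latent_class = ifelse(is_scalper, "scalper", "legitimate"),
    age_band = sample(names(config$group_attrs$age_band), n, replace = TRUE,
                      prob = config$group_attrs$age_band),
    socio_band = sample(names(config$group_attrs$socio_band), n, replace = TRUE,
                        prob = config$group_attrs$socio_band),
    region = sample(c("urban", "suburban", "rural"), n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2)),
    device_ids = purrr::map2(id, n_devices, function(a, k) paste0("dev_", a, "_", seq_len(k))),
    card_ids = purrr::map2(id, n_cards, function(a, k) paste0("card_", a, "_", seq_len(k))),
    ip_ids = purrr::map2(id, n_ips, function(a, k) paste0("ip_", a, "_", seq_len(k)))
  )
}

#' Simulate a registration event log
#'
#' Generates a schema-valid event stream for a cohort. Booking arrivals follow
#' a pooled Poisson process at `config$arrival_rate_per_day`; each booking is
#' attributed to an account with weight `scalper_activity_mult` for scalpers.
#' Legitimate bookings are spread over daytime hours with manual-speed
#' operation durations; scalper bookings are grouped into short automation
#' bursts near the midnight slot-release window, use sub-second operation
#' durations, and cancel at a high per-booking rate. Every booking is later
#' resolved by exactly one `cancel`, `complete` or `no_show` event referencing
#' it, so the log satisfies the completion/no-show accounting identity by
#' construction.
#'
#' @param cohort tibble from [simulate_cohort()].
#' @param config the same [sim_config()] used for the cohort.
#' @param seed optional integer overriding `config$seed + 1`.
#' @return a tibble of events ordered by timestamp with columns `event_id`,
#'   `account_id`, `device_id`, `ip`, `card_id`, `timestamp` (POSIXct UTC, ms
#'   resolution), `department`, `channel`, `action`, `op_duration_s`,
#'   `session_id`, `ref_event_id` (the booking a resolution event refers to).
#' @examples
#' cfg <- sim_config(n_accounts = 50, arrival_rate_per_day = 4, seed = 7)
#' events <- simulate_events(simulate_cohort(cfg), cfg)
#' dplyr::count(events, action)
#' @export
simulate_events <- function(cohort, config, seed = NULL) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a sim_config object",
          class = "scalpguard_config_error")
  }
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    abort("`cohort` must be a nonempty cohort tibble")
  }
  if (config$arrival_rate_per_day <= 0) abort("arrival rate must be > 0")
  set.seed(seed %||% (config$seed + 1L))

  t0 <- as.POSIXct(paste(config$period_start, "00:00:00"), tz = "UTC")
  t_int <- as.POSIXct(paste(config$intervention_date, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(config$period_end, "23:59:59"), tz = "UTC")
  horizon_days <- as.numeric(difftime(t1, t0, units = "days"))

  n_book <- rpois(1, config$arrival_rate_per_day * horizon_days)
  if (n_book == 0) {
    return(empty_event_log())
  }

  w <- ifelse(cohort$latent_class == "scalper", config$scalper_activity_mult, 1)
  acct_idx <- sample.int(nrow(cohort), n_book, replace = TRUE, prob = w)
  acct <- cohort[acct_idx, ]
  scalper <- acct$latent_class == "scalper"

  ## --- booking timestamps -------------------------------------------------
  ts <- rep(t0, n_book)
  n_legit <- sum(!scalper)
  if (n_legit > 0) {
    day <- runif(n_legit, 0, horizon_days)
    hour <- 8 + 13 * stats::rbeta(n_legit, 2, 2)      # daytime peak ~14:30
    ts[!scalper] <- t0 + round((floor(day) * 86400 + hour * 3600 +
                                  runif(n_legit, 0, 1)) * 1000) / 1000
  }
  if (any(scalper)) {
    # cluster each scalper account's bookings into release-hour bursts
    sc <- tibble(row = which(scalper), account_id = acct$account_id[scalper])
    sc <- sc |>
      group_by(.data$account_id) |>
      mutate(burst = sample.int(max(1L, ceiling(n() / config$burst_size)),
                                n(), replace = TRUE),
             pos = row_number()) |>
      ungroup()
    bursts <- distinct(sc, .data$account_id, .data$burst)
    bursts$burst_day <- floor(runif(nrow(bursts), 0, horizon_days))
    bursts$burst_sec <- runif(nrow(bursts), 0, 1800)  # 00:00-00:30 release
    sc <- left_join(sc, bursts, by = c("account_id", "burst"))
    gaps <- runif(nrow(sc), 2, 45)                    # seconds between ops
    offset <- stats::ave(gaps, paste(sc$account_id, sc$burst), FUN = cumsum)
    sc_ts <- t0 + round((sc$burst_day * 86400 + sc$burst_sec + offset) *
                          1000) / 1000
    ts[sc$row] <- pmin(sc_ts, t1)
  }

  ## --- post-period thinning (generator-side intervention effect) ----------
  keep <- rep(TRUE, n_book)
  thin <- config$intervention_effect$scalper_activity_mult
  if (thin < 1) {
    post_scalper <- scalper & ts >= t_int
    keep[post_scalper] <- runif(sum(post_scalper)) < thin
  }
  acct <- acct[keep, ]; scalper <- scalper[keep]; ts <- ts[keep]
  n_book <- sum(keep)
  if (n_book == 0) return(empty_event_log())

  ## --- per-booking attributes ---------------------------------------------
  pick1 <- function(lst) purrr::map_chr(lst, function(v) v[sample.int(length(v), 1)])
  device_id <- pick1(acct$device_ids)
  card_id <- pick1(acct$card_ids)
  ip <- pick1(acct$ip_ids)
  dept_names <- names(config$departments)
  department <- sample(dept_names, n_book, replace = TRUE,
                       prob = config$departments)
  hot <- dept_names[which.max(config$departments)]
  department[scalper] <- ifelse(runif(sum(scalper)) < 0.7, hot,
                                department[scalper])
  channel <- sample(names(config$channel_mix), n_book, replace = TRUE,
                    prob = config$channel_mix)
  channel[scalper] <- "online"
  op_dur <- numeric(n_book)
  op_dur[!scalper] <- rlnorm(sum(!scalper), config$legit_op_duration$meanlog,
                             config$legit_op_duration$sdlog)
  op_dur[scalper] <- rlnorm(sum(scalper), config$scalper_op_duration$meanlog,
                            config$scalper_op_duration$sdlog)

  books <- tibble(
    event_id = sprintf("b%07d", seq_len(n_book)),
    account_id = acct$account_id, device_id = device_id, ip = ip,
    card_id = card_id, timestamp = ts, department = department,
    channel = channel, action = "book",
    op_duration_s = round(op_dur, 3),
    ref_event_id = NA_character_,
    .latent = acct$latent_class)

  ## --- resolution: cancel / complete / no_show -----------------------------
  p_cancel <- ifelse(scalper, config$scalper_cancel_prob,
                     config$legit_cancel_prob)
  cancelled <- runif(n_book) < p_cancel
  slot <- pmin(ts + runif(n_book, 1, 14) * 86400, t1)
  comp_shift <- ifelse(ts >= t_int, config$intervention_effect$completion_shift, 0)
  p_complete <- pmin(1, pmax(0, ifelse(scalper, config$scalper_complete_prob,
                                       config$legit_complete_prob) + comp_shift))
  completed <- !cancelled & runif(n_book) < p_complete

  cancel_delay <- ifelse(scalper, rexp(n_book, 1 / (0.5 * 3600)),
                         rexp(n_book, 1 / (12 * 3600)))
  cancel_ts <- pmin(ts + pmax(cancel_delay, 1), slot, t1)
  cancel_dur <- numeric(n_book)
  cancel_dur[!scalper] <- rlnorm(sum(!scalper), config$legit_op_duration$meanlog,
                                 config$legit_op_duration$sdlog)
  cancel_dur[scalper] <- rlnorm(sum(scalper), config$scalper_op_duration$meanlog,
                                config$scalper_op_duration$sdlog)

  res_action <- ifelse(cancelled, "cancel",
                       ifelse(completed, "complete", "no_show"))
  res <- books
  res$event_id <- sprintf("r%07d", seq_len(n_book))
  res$timestamp <- as.POSIXct(ifelse(cancelled, cancel_ts, slot),
                              tz = "UTC", origin = "1970-01-01")
  res$action <- res_action
  res$op_duration_s <- round(ifelse(cancelled, cancel_dur, 0), 3)
  res$ref_event_id <- books$event_id

  events <- bind_rows(books, res)
  events <- assign_sessions(events)
  events <- arrange(events, .data$timestamp, .data$event_id)
  events$.latent <- NULL
  events
}

# Sessions: user-initiated actions (book/cancel) by the same account separated
# by gaps of <= 30 minutes share a session; system-side resolution events
# (complete/no_show) inherit the session of their booking.
assign_sessions <- function(events) {
  user <- events$action %in% c("book", "cancel")
  ue <- events[user, c("event_id", "account_id", "timestamp")]
  ue <- ue[order(ue$account_id, ue$timestamp), ]
  gap <- c(Inf, diff(as.numeric(ue$timestamp)))
  new_acct <- c(TRUE, ue$account_id[-1] != ue$account_id[-nrow(ue)])
  new_session <- new_acct | gap > 1800
  sess_num <- stats::ave(as.integer(new_session), ue$account_id, FUN = cumsum)
  ue$session_id <- paste0(ue$account_id, "_s", sess_num)
  events$session_id <- ue$session_id[match(events$event_id, ue$event_id)]
  sys <- !user
  events$session_id[sys] <- ue$session_id[match(events$ref_event_id[sys],
                                                ue$event_id)]
  events
}

empty_event_log <- function() {
  tibble(event_id = character(), account_id = character(),
         device_id = character(), ip = character(), card_id = character(),
         timestamp = as.POSIXct(character(), tz = "UTC"),
         department = character(), channel = character(), action = character(),
         op_duration_s = numeric(), session_id = character(),
         ref_event_id = character())
}

#' Validate a registration event log against the schema
#'
#' Checks column presence and types, nonnegative durations, timestamps, and
#' referential integrity (every `cancel`/`complete`/`no_show` resolves to an
#' earlier `book` event by the same account).
#'
#' @param events event tibble.
#' @return invisibly `TRUE`; aborts with a descriptive error otherwise.
#' @export
validate_event_log <- function(events) {
  needed <- c("event_id", "account_id", "device_id", "ip", "card_id",
              "timestamp", "department", "channel", "action", "op_duration_s",
              "session_id", "ref_event_id")
  missing <- setdiff(needed, names(events))
  if (length(missing) > 0) {
    abort(paste("event log missing columns:", paste(missing, collapse = ", ")))
  }
  if (nrow(events) == 0) return(invisible(TRUE))
  if (any(!events$action %in% c("book", "cancel", "complete", "no_show"))) {
    abort("unknown action value in event log")
  }
  if (any(events$op_duration_s < 0)) abort("negative op_duration_s")
  if (anyDuplicated(events$event_id)) abort("duplicate event_id")
  res <- events[events$action != "book", ]
  if (nrow(res) > 0) {
    m <- match(res$ref_event_id, events$event_id)
    if (anyNA(m)) abort("resolution event with missing booking reference")
    bk <- events[m, ]
    if (any(bk$action != "book")) abort("ref_event_id must point at a book event")
    if (any(bk$account_id != res$account_id)) {
      abort("resolution event references a booking by a different account")
    }
    if (any(bk$timestamp > res$timestamp)) {
      abort("resolution event precedes its booking")
    }
  }
  invisible(TRUE)
}
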