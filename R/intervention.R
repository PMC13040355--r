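#' Graduated intervention policy
#'
#' Flagged accounts are mapped to one of two graduated measures by posterior
#' band: additional verification (an SMS-style challenge-response that
#' legitimate users almost always pass) or a temporary booking restriction.
#' A per-account concurrent-booking cap models card–phone binding and
#' appointment quotas.
#'
#' @param verify_band half-open posterior interval `[lo, hi)` triggering the
#'   verification challenge (default `c(0.75, 0.90)`).
#' @param restrict_band closed posterior interval `[lo, hi]` triggering a
#'   temporary restriction (default `c(0.90, 1)`).
#' @param challenge_pass_prob_legit,challenge_pass_prob_scalper probability
#'   that a challenged account of each latent class passes the challenge
#'   (defaults 0.98 / 0.05).
#' @param restriction_duration_h duration of a booking restriction, hours.
#' @param booking_cap maximum simultaneously open bookings per account
#'   (default 3).
#' @return an object of class `intervention_policy`.
#' @export
intervention_policy <- function(verify_band = c(0.75, 0.90),
                                restrict_band = c(0.90, 1),
                                challenge_pass_prob_legit = 0.98,
                                challenge_pass_prob_scalper = 0.05,
                                restriction_duration_h = 72,
                                booking_cap = 3) {
  if (verify_band[1] >= verify_band[2] || restrict_band[1] > restrict_band[2]) {
    abort("bands must be ordered intervals", class = "scalpguard_config_error")
  }
  if (restrict_band[1] < verify_band[2] - 1e-12) {
    abort("verify and restrict bands overlap",
          class = "scalpguard_config_error")
  }
  for (p in c(challenge_pass_prob_legit, challenge_pass_prob_scalper)) {
    if (p < 0 || p > 1) abort("challenge pass probabilities must lie in [0, 1]")
  }
  structure(list(verify_band = verify_band, restrict_band = restrict_band,
                 challenge_pass_prob_legit = challenge_pass_prob_legit,
                 challenge_pass_prob_scalper = challenge_pass_prob_scalper,
                 restriction_duration_h = restriction_duration_h,
                 booking_cap = booking_cap),
            class = "intervention_policy")
}

#' Map risk scores to graduated intervention actions
#'
#' Deterministic band lookup: flagged scores with posterior in the verify
#' band get `"verify"`, in the restrict band `"restrict"`; passing scores get
#' `"none"`.
#'
#' @param scores tibble from [classify_accounts()].
#' @param policy an [intervention_policy()].
#' @return action-log tibble: `account_id`, `posterior`, `action`,
#'   `challenge` (unresolved `NA`), `final_status` (`"clear"` for unflagged,
#'   `"pending"` otherwise).
#' @export
apply_policy <- function(scores, policy) {
  stopifnot(inherits(policy, "intervention_policy"))
  vb <- policy$verify_band; rb <- policy$restrict_band
  action <- ifelse(scores$decision == "pass", "none",
                   ifelse(scores$posterior >= vb[1] & scores$posterior < vb[2],
                          "verify",
                          ifelse(scores$posterior >= rb[1] &
                                   scores$posterior <= rb[2],
                                 "restrict", "none")))
  tibble(account_id = scores$account_id, posterior = scores$posterior,
         action = action,
         challenge = NA_character_,
         final_status = ifelse(action == "none", "clear", "pending"))
}

#' Resolve verification challenges
#'
#' `verify` actions are resolved by a seeded Bernoulli draw with a pass
#' probability depending on the account's latent class: passing accounts
#' revert to unhindered status (`"cleared"`), failing accounts are blocked.
#' `restrict` actions are blocked outright for the restriction duration.
#'
#' @param action_log tibble from [apply_policy()].
#' @param cohort cohort tibble supplying `latent_class`.
#' @param policy an [intervention_policy()].
#' @param seed integer seed.
#' @return the action log with `challenge` (`"pass"`/`"fail"`) and
#'   `final_status` (`"clear"`, `"cleared"`, `"blocked"`) filled in.
#' @export
resolve_challenges <- function(action_log, cohort, policy, seed = 1) {
  set.seed(seed)
  log <- left_join(action_log,
                   cohort[, c("account_id", "latent_class")],
                   by = "account_id")
  p_pass <- ifelse(log$latent_class == "scalper",
                   policy$challenge_pass_prob_scalper,
                   policy$challenge_pass_prob_legit)
  u <- runif(nrow(log))
  verify <- log$action == "verify"
  log$challenge[verify] <- ifelse(u[verify] < p_pass[verify], "pass", "fail")
  log$final_status <- ifelse(
    log$action == "none", "clear",
    ifelse(log$action == "restrict", "blocked",
           ifelse(log$challenge == "pass", "cleared", "blocked")))
  log$latent_class <- NULL
  log
}

# Bookings exceeding the concurrent-open cap, per account (quota enforcement).
# A booking is open from its timestamp until its resolution event.
capped_bookings <- function(events, cap) {
  books <- events[events$action == "book", ]
  res <- events[events$action != "book", ]
  res_time <- setNames(as.numeric(res$timestamp), res$ref_event_id)
  blocked <- character(0)
  for (acct in unique(books$account_id)) {
    b <- books[books$account_id == acct, ]
    if (nrow(b) <= cap) next
    b <- b[order(b$timestamp), ]
    t <- as.numeric(b$timestamp)
    rt <- unname(res_time[b$event_id])
    rt[is.na(rt)] <- Inf
    for (i in seq_len(nrow(b))) {
      open <- sum(t < t[i] & rt > t[i] & seq_len(nrow(b)) < i)
      if (open >= cap) blocked <- c(blocked, b$event_id[i])
    }
  }
  blocked
}

#' Run the full pre/post intervention experiment
#'
#' End-to-end closed loop: simulate the cohort and event stream over the full
#' study window, train the classifier on the pre-intervention period (rule
#' labels, standardized features), obtain a congestion index from the queuing
#' model, score post-period accounts under the congestion-modulated dynamic
#' prior, apply the graduated policy with challenge resolution, block the
#' post-period bookings of restricted/failed accounts (plus quota-capped
#' bookings), materialize outcomes, and run the evaluation suite. The whole
#' experiment is a pure function of the configuration objects and `seed`.
#'
#' @param config a [sim_config()].
#' @param policy an [intervention_policy()], or `NULL` for no intervention
#'   (null experiment: the model still scores, nothing is blocked).
#' @param model list of classifier settings: `prior`, `threshold`,
#'   `lambda_reg`, `gain`.
#' @param queue list of queuing settings: `lambda`, `mu`, `servers`,
#'   `horizon` (hours) feeding [simulate_queue()] for the congestion index.
#' @param eval_config list: `bootstrap_B` (default 200).
#' @param seed integer master seed; all stages derive their streams from it.
#' @return object of class `scalp_experiment`: `outcome` (per-period outcome
#'   table), `evaluation` (list of test results, metrics, fairness, ITS,
#'   bootstrap), `scores`, `action_log`, `fit`, `seed`.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_accounts = 600, arrival_rate_per_day = 8, seed = 2)
#' ex <- run_experiment(cfg, intervention_policy())
#' ex$outcome
#' }
#' @export
run_experiment <- function(config, policy = intervention_policy(),
                           model = list(prior = 0.05, threshold = 0.75,
                                        lambda_reg = 0.1, gain = 2),
                           queue = list(lambda = 8, mu = 1, servers = 10,
                                        horizon = 2000),
                           eval_config = list(bootstrap_B = 200),
                           seed = config$seed) {
  stage <- "setup"
  wrap <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      abort(sprintf("experiment failed at stage '%s': %s", name,
                    conditionMessage(e)))
    })
  }
  seeds <- derive_seeds(seed, c("cohort", "events", "labels", "queue",
                                "challenge", "bootstrap"))
  cohort <- wrap("simulate", simulate_cohort(config, seed = seeds["cohort"]))
  events <- wrap("simulate", simulate_events(cohort, config,
                                             seed = seeds["events"]))
  t_int <- as.POSIXct(paste(config$intervention_date, "00:00:00"), tz = "UTC")

  # period of a booking = period of its book event; resolutions follow it
  books <- events[events$action == "book", ]
  period_of_booking <- setNames(
    ifelse(books$timestamp < t_int, "pre", "post"), books$event_id)
  events$period <- ifelse(events$action == "book",
                          period_of_booking[events$event_id],
                          period_of_booking[events$ref_event_id])

  pre <- events[events$period == "pre", names(events) != "period"]
  post <- events[events$period == "post", names(events) != "period"]

  labels_pre <- wrap("label", label_accounts(
    pre, label_noise = config$label_noise, seed = seeds["labels"]))
  dm_pre <- wrap("features", build_design_matrix(pre, labels_pre, cohort))
  fit <- wrap("fit", scalper_bayes(dm_pre, prior = model$prior,
                                   threshold = model$threshold,
                                   lambda_reg = model$lambda_reg))

  qm <- wrap("queue", simulate_queue(queue$lambda, queue$mu, queue$servers,
                                     horizon = queue$horizon,
                                     seed = seeds["queue"]))
  cong <- congestion_index(qm)

  labels_post <- wrap("label", label_accounts(post))
  dm_post <- wrap("features", build_design_matrix(
    post, labels_post, cohort, center = fit$center, scale = fit$scale))
  scores <- wrap("deploy", classify_accounts(fit, dm_post, congestion = cong,
                                             gain = model$gain))

  if (is.null(policy)) {
    action_log <- tibble(account_id = scores$account_id,
                         posterior = scores$posterior, action = "none",
                         challenge = NA_character_, final_status = "clear")
    blocked_accounts <- character(0)
    capped <- character(0)
  } else {
    action_log <- wrap("policy", apply_policy(scores, policy))
    action_log <- wrap("policy", resolve_challenges(action_log, cohort, policy,
                                                    seed = seeds["challenge"]))
    blocked_accounts <- action_log$account_id[action_log$final_status ==
                                                "blocked"]
    capped <- wrap("policy", capped_bookings(
      post[!post$account_id %in% blocked_accounts, ], policy$booking_cap))
  }

  post_books <- post[post$action == "book", ]
  blocked_ids <- union(post_books$event_id[post_books$account_id %in%
                                             blocked_accounts], capped)

  outcome <- bind_rows(
    materialize_outcomes(pre, "pre", character(0), events, cohort,
                         action_log),
    materialize_outcomes(post, "post", blocked_ids, events, cohort,
                         action_log))

  evaluation <- wrap("evaluate", evaluate_experiment(
    pre, post, blocked_ids, outcome, scores, labels_post, cohort, t_int,
    boot_seed = seeds["bootstrap"],
    bootstrap_B = eval_config$bootstrap_B %||% 200))

  structure(list(outcome = outcome, evaluation = evaluation, scores = scores,
                 action_log = action_log, fit = fit, queue_metrics = qm,
                 congestion = cong, seed = seed, config = config),
            class = "scalp_experiment")
}

# Per-period outcome accounting. Blocked bookings are intercepted at booking
# time: they and their resolutions leave the materialized stream.
materialize_outcomes <- function(period_events, period, blocked_ids, all_events,
                                 cohort, action_log) {
  books <- period_events[period_events$action == "book", ]
  res <- period_events[period_events$action != "book", ]
  blocked <- books$event_id %in% blocked_ids
  live_books <- books[!blocked, ]
  live_res <- res[!res$ref_event_id %in% blocked_ids, ]

  flagged <- action_log$account_id[action_log$action != "none"]
  legit <- cohort$account_id[cohort$latent_class == "legitimate"]

  # first-time share: bookings by accounts whose first booking in the whole
  # log falls inside this period
  all_books <- all_events[all_events$action == "book", ]
  first_ts <- tapply(as.numeric(all_books$timestamp), all_books$account_id, min)
  lo <- min(as.numeric(books$timestamp)); hi <- max(as.numeric(books$timestamp))
  first_in_period <- names(first_ts)[first_ts >= lo & first_ts <= hi]

  tibble(
    period = period,
    bookings = nrow(books),
    blocked_bookings = sum(blocked),
    materialized = nrow(live_res),
    completions = sum(live_res$action == "complete"),
    cancels = sum(live_res$action == "cancel"),
    no_shows = sum(live_res$action == "no_show"),
    completion_rate = sum(live_res$action == "complete") /
      max(1, sum(live_res$action != "cancel")),
    no_show_rate = sum(live_res$action == "no_show") /
      max(1, sum(live_res$action != "cancel")),
    flagged_accounts = if (period == "post") length(flagged) else NA_integer_,
    wrongly_flagged_legit = if (period == "post")
      length(intersect(flagged, legit)) else NA_integer_,
    first_time_share = mean(live_books$account_id %in% first_in_period),
    online_share = mean(live_books$channel == "online"),
    onsite_share = mean(live_books$channel == "onsite"),
    telephone_share = mean(live_books$channel == "telephone"))
}

evaluate_experiment <- function(pre, post, blocked_ids, outcome, scores,
                                labels_post, cohort, t_int, boot_seed,
                                bootstrap_B) {
  o_pre <- outcome[outcome$period == "pre", ]
  o_post <- outcome[outcome$period == "post", ]

  tab <- matrix(c(o_pre$completions, o_pre$no_shows,
                  o_post$completions, o_post$no_shows),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("pre", "post"), c("completed", "no_show")))
  chi <- suppressWarnings(chi_square_test(tab))
  rr <- risk_ratio(o_pre$completions, o_pre$completions + o_pre$no_shows,
                   o_post$completions, o_post$completions + o_post$no_shows)

  truth <- labels_post$label[match(scores$account_id, labels_post$account_id)]
  cm <- confusion_metrics(truth, ifelse(scores$decision == "flag",
                                        "abnormal", "normal"),
                          scores = scores$posterior, positive = "abnormal")
  grp <- cohort[match(scores$account_id, cohort$account_id), ]
  fair_age <- suppressWarnings(equal_opportunity_gap(
    truth, ifelse(scores$decision == "flag", "abnormal", "normal"),
    grp$age_band, positive = "abnormal"))
  fair_socio <- suppressWarnings(equal_opportunity_gap(
    truth, ifelse(scores$decision == "flag", "abnormal", "normal"),
    grp$socio_band, positive = "abnormal"))

  # monthly completion series for the ITS fit (materialized bookings only)
  live <- bind_rows(pre[pre$action %in% c("complete", "no_show"), ],
                    post[post$action %in% c("complete", "no_show") &
                           !post$ref_event_id %in% blocked_ids, ])
  month <- format(live$timestamp, "%Y-%m")
  months <- sort(unique(month))
  series <- tibble(
    time = seq_along(months),
    value = as.numeric(tapply(live$action == "complete", month, mean)[months]))
  int_month <- sum(as.Date(paste0(months, "-01")) <
                     as.Date(t_int)) + 1
  its <- tryCatch(its_fit(series, int_month), error = function(e) NULL)

  # bootstrap CI for the pre->post completion-rate change (percentage points)
  rec <- tibble(
    post = c(rep(0, o_pre$completions + o_pre$no_shows),
             rep(1, o_post$completions + o_post$no_shows)),
    completed = c(rep(1, o_pre$completions), rep(0, o_pre$no_shows),
                  rep(1, o_post$completions), rep(0, o_post$no_shows)))
  boot <- bootstrap_ci(rec, function(d) {
    100 * (mean(d$completed[d$post == 1]) - mean(d$completed[d$post == 0]))
  }, B = bootstrap_B, seed = boot_seed)

  # effectiveness: materialized bookings by flagged accounts, pre vs post
  flagged <- scores$account_id[scores$decision == "flag"]
  pre_flagged <- sum(pre$action == "book" & pre$account_id %in% flagged)
  post_books <- post[post$action == "book", ]
  post_flagged_live <- sum(post_books$account_id %in% flagged &
                             !post_books$event_id %in% blocked_ids)
  drop_pct <- if (pre_flagged > 0) {
    100 * (1 - post_flagged_live / pre_flagged)
  } else NA_real_

  n_legit_scored <- sum(grp$latent_class == "legitimate", na.rm = TRUE)
  fp_share <- 100 * sum(scores$decision == "flag" &
                          grp$latent_class == "legitimate", na.rm = TRUE) /
    max(1, n_legit_scored)

  list(completion_chisq = chi, completion_rr = rr,
       completion_change_pp = 100 * (o_post$completion_rate -
                                       o_pre$completion_rate),
       confusion = cm, fairness_age = fair_age, fairness_socio = fair_socio,
       its = its, bootstrap_completion = boot,
       flagged_booking_drop_pct = drop_pct,
       wrongly_flagged_legit_pct = fp_share)
}

#' @export
print.scalp_experiment <- function(x, ...) {
  cat("<scalp_experiment>\n")
  print(x$outcome[, c("period", "bookings", "blocked_bookings",
                      "completion_rate", "no_show_rate")])
  ev <- x$evaluation
  cat(sprintf("  completion change: %+.1f pp; RR %.3f; flagged-booking drop %.1f%%\n",
              ev$completion_change_pp, ev$completion_rr$rr,
              ev$flagged_booking_drop_pct))
  cat(sprintf("  wrongly flagged legitimate accounts: %.2f%%\n",
              ev$wrongly_flagged_legit_pct))
  invisible(x)
}

#' Plot pre/post outcome rates of an experiment
#'
#' @param experiment a `scalp_experiment` object.
#' @return a ggplot bar chart of completion and no-show rates by period.
#' @export
plot_outcomes <- function(experiment) {
  d <- experiment$outcome |>
    select("period", "completion_rate", "no_show_rate") |>
    tidyr::pivot_longer(-"period", names_to = "outcome", values_to = "rate")
  d$period <- factor(d$period, levels = c("pre", "post"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$period, y = .data$rate,
                                  fill = .data$outcome)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Appointment outcomes before and after intervention") +
    ggplot2::theme_minimal()
}
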