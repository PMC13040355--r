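#' Simulation configuration for synthetic registration streams
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cohort()] and [simulate_events()]. Defaults encode the study
#' conditions the analysis assumes: a 5% baseline scalper prevalence, scalper
#' operation speeds with a heavy sub-2-second mass (lognormal median 0.8 s
#' versus 25 s for manual users), device-to-card fan-out above five cards,
#' cancelation bursts at slot-release time, and a 2019--2022 observation
#' window interrupted on 2021-01-01.
#'
#' @param n_accounts number of simulated accounts.
#' @param scalper_fraction probability that an account is a scalper
#'   (default 0.05, the audited baseline prevalence).
#' @param period_start,intervention_date,period_end calendar dates delimiting
#'   the pre/post observation periods (`period_start < intervention_date <
#'   period_end`).
#' @param arrival_rate_per_day Poisson intensity of booking arrivals, per day,
#'   pooled over all accounts.
#' @param legit_op_duration,scalper_op_duration lognormal parameters
#'   (`meanlog`, `sdlog`) for operation completion times in seconds. The
#'   scalper default puts most mass below the 2 s automation signature.
#' @param legit_cancel_prob,scalper_cancel_prob per-booking cancelation
#'   probabilities.
#' @param legit_complete_prob,scalper_complete_prob probability that a booking
#'   that survives cancelation is completed (the remainder become no-shows).
#' @param scalper_cards_per_device list with `support` and `prob`: the
#'   distribution of distinct medical-card IDs attached to a scalper device.
#'   Default support 6--12, i.e. mass strictly above the 5-card threshold.
#' @param scalper_activity_mult booking-rate multiplier of a scalper account
#'   relative to a legitimate one.
#' @param channel_mix named probability vector over
#'   `c("online", "onsite", "telephone")` for legitimate bookings; scalpers
#'   book online only.
#' @param departments named numeric vector of department weights.
#' @param group_attrs list with named probability vectors `age_band` and
#'   `socio_band` for the demographic strata used in fairness reporting.
#' @param label_noise probability that a ground-truth label is flipped before
#'   manual verification (default 0 = audited labels are exact).
#' @param intervention_effect list describing how the generator itself changes
#'   after `intervention_date` when producing observational (non-modelled)
#'   pre/post tables: `scalper_activity_mult` thins (\eqn{<1}) post-period
#'   scalper bookings, `completion_shift` is added to the legitimate
#'   completion probability. Defaults are neutral.
#' @param burst_size target number of bookings per scalper burst session.
#' @param seed integer seed recorded in the config and used by the
#'   generators unless overridden.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_accounts = 200, arrival_rate_per_day = 5, seed = 42)
#' cohort <- simulate_cohort(cfg)
#' table(cohort$latent_class)
#' @export
sim_config <- function(n_accounts = 2000,
                       scalper_fraction = 0.05,
                       period_start = as.Date("2019-01-01"),
                       intervention_date = as.Date("2021-01-01"),
                       period_end = as.Date("2022-12-31"),
                       arrival_rate_per_day = 15,
                       legit_op_duration = list(meanlog = log(25), sdlog = 0.9),
                       scalper_op_duration = list(meanlog = log(0.8), sdlog = 0.35),
                       legit_cancel_prob = 0.12,
                       scalper_cancel_prob = 0.75,
                       legit_complete_prob = 0.75,
                       scalper_complete_prob = 0.05,
                       scalper_cards_per_device = list(support = 6:12,
                                                       prob = rep(1 / 7, 7)),
                       scalper_activity_mult = 8,
                       channel_mix = c(online = 0.8, onsite = 0.15,
                                       telephone = 0.05),
                       departments = c(internal_medicine = 0.3, surgery = 0.2,
                                       pediatrics = 0.15, dermatology = 0.1,
                                       cardiology = 0.1, orthopedics = 0.08,
                                       ophthalmology = 0.04, dentistry = 0.03),
                       group_attrs = list(
                         age_band = c(`18-34` = 0.35, `35-54` = 0.4,
                                      `55+` = 0.25),
                         socio_band = c(low = 0.3, mid = 0.5, high = 0.2)),
                       label_noise = 0,
                       intervention_effect = list(scalper_activity_mult = 1,
                                                  completion_shift = 0),
                       burst_size = 6,
                       seed = 1L) {
  cfg <- list(
    n_accounts = n_accounts, scalper_fraction = scalper_fraction,
    period_start = as.Date(period_start),
    intervention_date = as.Date(intervention_date),
    period_end = as.Date(period_end),
    arrival_rate_per_day = arrival_rate_per_day,
    legit_op_duration = legit_op_duration,
    scalper_op_duration = scalper_op_duration,
    legit_cancel_prob = legit_cancel_prob,
    scalper_cancel_prob = scalper_cancel_prob,
    legit_complete_prob = legit_complete_prob,
    scalper_complete_prob = scalper_complete_prob,
    scalper_cards_per_device = scalper_cards_per_device,
    scalper_activity_mult = scalper_activity_mult,
    channel_mix = channel_mix, departments = departments,
    group_attrs = group_attrs, label_noise = label_noise,
    intervention_effect = intervention_effect,
    burst_size = burst_size, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, msg) {
    abort(sprintf("invalid sim_config field '%s': %s", field, msg),
          class = "scalpguard_config_error")
  }
  if (!is.numeric(cfg$n_accounts) || cfg$n_accounts < 1 ||
      cfg$n_accounts != round(cfg$n_accounts)) {
    bad("n_accounts", "must be a positive integer")
  }
  if (cfg$scalper_fraction < 0 || cfg$scalper_fraction > 1) {
    bad("scalper_fraction", "must lie in [0, 1]")
  }
  if (!(cfg$period_start < cfg$intervention_date &&
        cfg$intervention_date < cfg$period_end)) {
    bad("intervention_date",
        "dates must satisfy period_start < intervention_date < period_end")
  }
  if (cfg$arrival_rate_per_day <= 0) {
    bad("arrival_rate_per_day", "must be > 0")
  }
  for (f in c("legit_op_duration", "scalper_op_duration")) {
    p <- cfg[[f]]
    if (!is.list(p) || is.null(p$meanlog) || is.null(p$sdlog) || p$sdlog <= 0) {
      bad(f, "must be list(meanlog=, sdlog=) with sdlog > 0")
    }
  }
  for (f in c("legit_cancel_prob", "scalper_cancel_prob",
              "legit_complete_prob", "scalper_complete_prob", "label_noise")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) bad(f, "must lie in [0, 1]")
  }
  cards <- cfg$scalper_cards_per_device
  if (!is.list(cards) || length(cards$support) != length(cards$prob)) {
    bad("scalper_cards_per_device", "must be list(support=, prob=) of equal length")
  }
  tryCatch(check_prob_vector(cards$prob, "scalper_cards_per_device$prob"),
           error = function(e) bad("scalper_cards_per_device", conditionMessage(e)))
  tryCatch(check_prob_vector(cfg$channel_mix, "channel_mix"),
           error = function(e) bad("channel_mix", conditionMessage(e)))
  if (!setequal(names(cfg$channel_mix), c("online", "onsite", "telephone"))) {
    bad("channel_mix", "must be named over online/onsite/telephone")
  }
  if (any(cfg$departments <= 0) || is.null(names(cfg$departments))) {
    bad("departments", "must be a named vector of positive weights")
  }
  for (g in c("age_band", "socio_band")) {
    tryCatch(check_prob_vector(cfg$group_attrs[[g]], g),
             error = function(e) bad("group_attrs", conditionMessage(e)))
  }
  if (cfg$scalper_activity_mult <= 0) bad("scalper_activity_mult", "must be > 0")
  ie <- cfg$intervention_effect
  if (ie$scalper_activity_mult < 0 || ie$scalper_activity_mult > 1) {
    bad("intervention_effect",
        "scalper_activity_mult must lie in [0, 1] (post-period thinning)")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  accounts: %d (scalper fraction %.3f)\n",
              x$n_accounts, x$scalper_fraction))
  cat(sprintf("  period: %s -> %s (intervention %s)\n",
              x$period_start, x$period_end, x$intervention_date))
  cat(sprintf("  arrivals: %.2f bookings/day; seed %d\n",
              x$arrival_rate_per_day, x$seed))
  invisible(x)
}
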