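fake_scores <- function(post) {
  tibble::tibble(account_id = sprintf("a%02d", seq_along(post)),
                 posterior = post,
                 effective_prior = 0.05,
                 decision = ifelse(post >= 0.75, "flag", "pass"))
}

test_that("policy bands map posteriors to graduated actions", {
  pol <- intervention_policy()
  log <- apply_policy(fake_scores(c(0.60, 0.75, 0.80, 0.8999, 0.90, 0.95, 1)),
                      pol)
  expect_equal(log$action,
               c("none", "verify", "verify", "verify", "restrict", "restrict",
                 "restrict"))
  expect_equal(log$final_status,
               ifelse(log$action == "none", "clear", "pending"))
  expect_true(all(is.na(log$challenge)))
})

test_that("malformed policies are rejected at construction", {
  expect_error(intervention_policy(verify_band = c(0.9, 0.75)), "ordered",
               class = "scalpguard_config_error")
  expect_error(intervention_policy(verify_band = c(0.5, 0.9),
                                   restrict_band = c(0.8, 1)),
               "overlap", class = "scalpguard_config_error")
  expect_error(intervention_policy(challenge_pass_prob_legit = 1.5), "0, 1")
})

test_that("challenge resolution honours the pass-probability limits", {
  scores <- fake_scores(rep(0.8, 10))  # all in the verify band
  cohort <- tibble::tibble(account_id = scores$account_id,
                           latent_class = rep(c("legitimate", "scalper"), 5))
  pol_all <- intervention_policy(challenge_pass_prob_legit = 1,
                                 challenge_pass_prob_scalper = 1)
  res <- resolve_challenges(apply_policy(scores, pol_all), cohort, pol_all)
  expect_true(all(res$challenge == "pass"))
  expect_true(all(res$final_status == "cleared"))

  pol_none <- intervention_policy(challenge_pass_prob_legit = 0,
                                  challenge_pass_prob_scalper = 0)
  res0 <- resolve_challenges(apply_policy(scores, pol_none), cohort, pol_none)
  expect_true(all(res0$challenge == "fail"))
  expect_true(all(res0$final_status == "blocked"))

  # restrictions block outright, no challenge drawn
  resr <- resolve_challenges(apply_policy(fake_scores(rep(0.95, 4)),
                                          pol_all),
                             cohort[1:4, ], pol_all)
  expect_true(all(resr$action == "restrict"))
  expect_true(all(resr$final_status == "blocked"))

  # resolution is deterministic under a fixed seed
  pol <- intervention_policy()
  a <- resolve_challenges(apply_policy(scores, pol), cohort, pol, seed = 5)
  b <- resolve_challenges(apply_policy(scores, pol), cohort, pol, seed = 5)
  expect_equal(a, b)
})

test_that("the booking cap blocks bookings beyond the open quota", {
  # five bookings, none resolved: with cap 3 the 4th and 5th are blocked
  ev <- make_events(data.frame(action = rep("book", 5),
                               timestamp = hours_ts(1:5)))
  expect_equal(capped_bookings(ev, 3), c("e0004", "e0005"))
  # resolving early bookings frees quota
  ev2 <- make_events(data.frame(
    action = c("book", "book", "book", "cancel", "book"),
    timestamp = hours_ts(1:5),
    ref_event_id = c(NA, NA, NA, "e0001", NA)))
  expect_equal(capped_bookings(ev2, 3), character(0))
  expect_equal(capped_bookings(ev, 10), character(0))
})

test_that("experiment outcomes conserve bookings and resolutions", {
  cfg <- sim_config(n_accounts = 600, arrival_rate_per_day = 8,
                    period_start = as.Date("2020-01-01"),
                    intervention_date = as.Date("2020-07-01"),
                    period_end = as.Date("2020-12-31"), seed = 2)
  ex <- run_experiment(cfg, intervention_policy())
  out <- ex$outcome
  expect_equal(out$period, c("pre", "post"))
  # every materialized booking resolves exactly once
  expect_equal(out$completions + out$cancels + out$no_shows, out$materialized)
  expect_equal(out$materialized, out$bookings - out$blocked_bookings)
  expect_equal(out$blocked_bookings[out$period == "pre"], 0)
  expect_true(all(out$completion_rate >= 0 & out$completion_rate <= 1))
  # channel shares are a probability vector
  shares <- out$online_share + out$onsite_share + out$telephone_share
  expect_equal(shares, c(1, 1))
  expect_s3_class(plot_outcomes(ex), "ggplot")
  expect_output(print(ex), "scalp_experiment")

  # the policy run is deterministic end to end
  ex2 <- run_experiment(cfg, intervention_policy())
  expect_equal(ex$outcome, ex2$outcome)
  expect_equal(ex$scores, ex2$scores)
  expect_equal(ex$evaluation$completion_change_pp,
               ex2$evaluation$completion_change_pp)
})

test_that("a null experiment shows no spurious intervention effect", {
  cfg <- sim_config(n_accounts = 600, arrival_rate_per_day = 8,
                    period_start = as.Date("2020-01-01"),
                    intervention_date = as.Date("2020-07-01"),
                    period_end = as.Date("2020-12-31"), seed = 2)
  null_ex <- run_experiment(cfg, policy = NULL)
  expect_equal(sum(null_ex$outcome$blocked_bookings), 0)
  expect_true(all(null_ex$action_log$action == "none"))
  # no intervention happened, so pre/post completion should not differ
  expect_gt(null_ex$evaluation$completion_chisq$p_value, 0.01)
  expect_lt(abs(null_ex$evaluation$completion_change_pp), 5)

  # the graduated policy lifts post-period completion above the null run
  pol_ex <- run_experiment(cfg, intervention_policy())
  expect_gt(pol_ex$outcome$completion_rate[pol_ex$outcome$period == "post"],
            null_ex$outcome$completion_rate[null_ex$outcome$period == "post"])
  expect_gt(sum(pol_ex$outcome$blocked_bookings), 0)
})
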