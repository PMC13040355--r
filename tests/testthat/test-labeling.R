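test_that("sliding-window cancel maximum matches hand-worked cases", {
  ev <- make_events(data.frame(action = "cancel",
                               timestamp = hours_ts(c(0, 10, 20, 47))))
  expect_equal(max_cancels_in_window(ev, "a1"), 4)

  ev2 <- make_events(data.frame(action = "cancel",
                                timestamp = hours_ts(c(0, 47.9, 48.1, 96))))
  expect_equal(max_cancels_in_window(ev2, "a1"), 2)

  books <- make_events(data.frame(action = "book"))
  expect_equal(max_cancels_in_window(books, "a1"), 0)
  expect_equal(max_cancels_in_window(books, "ghost"), 0)
})

test_that("sliding-window maximum equals brute-force window enumeration", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(1:50, 1)
    times <- sort(runif(n, 0, 200)) * 3600
    ev <- make_events(data.frame(
      action = "cancel", timestamp = hours_ts(times / 3600)))
    expect_equal(max_cancels_in_window(ev, "a1", window_hours = 48),
                 brute_max_in_window(as.numeric(ev$timestamp), 48 * 3600))
  }
})

test_that("adding a cancel never decreases the window maximum", {
  set.seed(55)
  for (i in 1:10) {
    times <- sort(runif(20, 0, 500))
    base <- make_events(data.frame(action = "cancel",
                                   timestamp = hours_ts(times)))
    more <- make_events(data.frame(action = "cancel",
                                   timestamp = hours_ts(c(times,
                                                          runif(1, 0, 500)))))
    expect_gte(max_cancels_in_window(more, "a1"),
               max_cancels_in_window(base, "a1"))
  }
})

test_that("card fan-out counts distinct cards per device", {
  ev <- make_events(data.frame(card_id = paste0("c", 1:6)))
  fan <- cards_per_device(ev)
  expect_equal(fan$n_cards[fan$device_id == "d1"], 6)

  ev1 <- make_events(data.frame(card_id = rep("c1", 5)))
  expect_equal(cards_per_device(ev1)$n_cards, 1)

  empty <- make_events(data.frame(action = character(0),
                                  timestamp = hours_ts(numeric(0))))
  expect_equal(nrow(cards_per_device(empty)), 0)
})

test_that("speed threshold takes the fast tail and honours a fixed override", {
  ev <- make_events(data.frame(op_duration_s = 1:100))
  expect_lte(speed_threshold(ev, percentile = 99), 2)
  expect_equal(speed_threshold(ev, percentile = 99),
               unname(quantile(1:100, 0.01)))

  flat <- make_events(data.frame(op_duration_s = rep(30, 10)))
  expect_equal(speed_threshold(flat), 30)

  expect_equal(speed_threshold(ev, fixed = 2.0), 2.0)
  none <- make_events(data.frame(action = rep("no_show", 3)))
  expect_error(speed_threshold(none), "no reference")
})

test_that("accounts are abnormal iff at least two criteria fire", {
  # two criteria: a cancel burst and 6-card device fan-out
  burst <- make_events(data.frame(
    action = c("cancel", "cancel", "cancel", "cancel", rep("book", 6)),
    timestamp = hours_ts(c(1, 2, 3, 4, 11:16)),
    card_id = c(rep("c1", 4), paste0("c", 1:6)),
    op_duration_s = 20))
  lab <- label_accounts(burst)
  expect_equal(lab$label, "abnormal")
  expect_true(lab$cancel_burst && lab$card_fanout)

  # a single criterion is not enough
  only_burst <- make_events(data.frame(
    action = rep("cancel", 4), timestamp = hours_ts(1:4),
    op_duration_s = 20))
  lab1 <- label_accounts(only_burst)
  expect_equal(lab1$label, "normal")
  expect_true(lab1$cancel_burst)

  # an account with no events is normal with all flags false
  lab2 <- label_accounts(only_burst, accounts = c("a1", "zz"))
  row <- lab2[lab2$account_id == "zz", ]
  expect_equal(row$label, "normal")
  expect_false(row$cancel_burst || row$card_fanout || row$fast_ops)
})

test_that("thresholds are strict: exactly 3 cancels or 5 cards do not flag", {
  ev3 <- make_events(data.frame(action = rep("cancel", 3),
                                timestamp = hours_ts(1:3), op_duration_s = 20))
  expect_false(label_accounts(ev3)$cancel_burst)
  ev5 <- make_events(data.frame(card_id = paste0("c", 1:5)))
  expect_false(label_accounts(ev5)$card_fanout)
})

test_that("a fan-out device marks every account that used it", {
  ev <- make_events(data.frame(
    account_id = c(rep("a1", 6), "a2"),
    card_id = c(paste0("c", 1:6), "c9"),
    session_id = c(rep("s1", 6), "s2")))
  lab <- label_accounts(ev)
  expect_true(all(lab$card_fanout))
})

test_that("labeling is invariant to event-log permutation", {
  cfg <- small_config(seed = 21)
  ev <- simulate_events(simulate_cohort(cfg), cfg)
  set.seed(1)
  shuffled <- ev[sample(nrow(ev)), ]
  expect_equal(label_accounts(ev), label_accounts(shuffled))
})
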