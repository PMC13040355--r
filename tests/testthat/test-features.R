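test_that("feature values match hand-worked single-account logs", {
  # three ops spaced exactly 2 s apart -> mean inter-operation interval 2.0
  ev <- make_events(data.frame(
    action = c("book", "book", "book"),
    timestamp = hours_ts(0) + c(0, 2, 4),
    session_id = "s1"))
  fx <- extract_features_all(ev)
  expect_equal(fx$mean_interop_s, 2.0)
  # one department only -> entropy exactly 0
  expect_equal(fx$dept_entropy, 0)
  # session duration = last - first timestamp = 4 s
  expect_equal(fx$mean_session_s, 4)
  expect_equal(fx$history_days, 4 / 86400)

  # 10 bookings, 4 cancels -> cancel_ratio 0.4
  ev2 <- make_events(data.frame(
    action = c(rep("book", 10), rep("cancel", 4)),
    timestamp = hours_ts(seq(0, 13) * 100),
    ref_event_id = c(rep(NA, 10), sprintf("e%04d", 1:4))))
  fx2 <- extract_features_all(ev2)
  expect_equal(fx2$cancel_ratio, 0.4)
  # the 4 cancels are 100 h apart, so no 48 h window holds more than one
  expect_equal(fx2$max_cancels_48h, 1)

  # clustered cancels: all 3 within one 48 h window
  ev3 <- make_events(data.frame(
    action = c("book", "book", "book", "cancel", "cancel", "cancel"),
    timestamp = hours_ts(c(0, 200, 400, 10, 20, 30)),
    ref_event_id = c(NA, NA, NA, "e0001", "e0002", "e0003")))
  expect_equal(extract_features_all(ev3)$max_cancels_48h, 3)
})

test_that("degenerate accounts get the documented fallback values", {
  one <- make_events(data.frame(action = "book", timestamp = hours_ts(1),
                                op_duration_s = 7))
  fx <- extract_features_all(one)
  expect_equal(fx$mean_interop_s, 86400)
  expect_equal(fx$mean_session_s, 7)  # one-event session: its op duration
  expect_equal(fx$history_days, 0)
  expect_equal(fx$bookings_per_day, 1)
})

test_that("features are a pure function of the event multiset", {
  cfg <- small_config(seed = 31)
  ev <- simulate_events(simulate_cohort(cfg), cfg)
  set.seed(2)
  shuffled <- ev[sample(nrow(ev)), ]
  expect_equal(extract_features_all(ev) |> dplyr::arrange(account_id),
               extract_features_all(shuffled) |> dplyr::arrange(account_id))
  # single-account extraction agrees with the full table
  acc <- ev$account_id[1]
  expect_equal(extract_features(ev, acc),
               extract_features_all(ev)[
                 extract_features_all(ev)$account_id == acc, ])
})

test_that("design matrix is standardized with recoverable parameters", {
  cfg <- small_config(seed = 13)
  co <- simulate_cohort(cfg)
  ev <- simulate_events(co, cfg)
  dm <- build_design_matrix(ev, label_accounts(ev), cohort = co)
  feats <- feature_names()
  expect_named(attr(dm, "center"), feats)
  expect_named(attr(dm, "scale"), feats)
  mus <- vapply(dm[feats], mean, numeric(1))
  sds <- vapply(dm[feats], sd, numeric(1))
  expect_true(all(abs(mus) < 1e-10))
  varying <- attr(dm, "scale") != 1 |
    vapply(dm[feats], function(v) sd(v) > 0, logical(1))
  expect_true(all(abs(sds[varying] - 1) < 1e-10))
  # replaying the stored transform on the raw matrix reproduces it exactly
  raw <- build_design_matrix(ev, label_accounts(ev), standardize = FALSE)
  replay <- build_design_matrix(ev, label_accounts(ev),
                                center = attr(dm, "center"),
                                scale = attr(dm, "scale"))
  expect_equal(design_matrix_features(replay), design_matrix_features(dm))
  expect_equal(
    (design_matrix_features(raw)[, 4] - attr(dm, "center")[4]) /
      attr(dm, "scale")[4],
    design_matrix_features(dm)[, 4])
})

test_that("design matrix has the contracted shape", {
  cfg <- small_config(seed = 17)
  ev <- simulate_events(simulate_cohort(cfg), cfg)
  dm <- build_design_matrix(ev, label_accounts(ev))
  expect_s3_class(dm, "design_matrix")
  expect_true(all(c("account_id", "label", feature_names()) %in% names(dm)))
  expect_equal(nrow(dm), dplyr::n_distinct(ev$account_id))
  expect_false(anyNA(design_matrix_features(dm)))
})

test_that("classes separate in the expected directions on simulated data", {
  cfg <- sim_config(n_accounts = 2000, arrival_rate_per_day = 15, seed = 23)
  co <- simulate_cohort(cfg)
  ev <- simulate_events(co, cfg)
  fx <- extract_features_all(ev) |>
    dplyr::left_join(co[, c("account_id", "latent_class")], by = "account_id")
  sc <- fx$latent_class == "scalper"
  expect_gt(mean(fx$max_cancels_48h[sc]), mean(fx$max_cancels_48h[!sc]))
  expect_gt(mean(fx$max_card_fanout[sc]), mean(fx$max_card_fanout[!sc]))
  expect_gt(mean(fx$cancel_ratio[sc]), mean(fx$cancel_ratio[!sc]))
  expect_lt(mean(fx$min_op_s[sc]), mean(fx$min_op_s[!sc]))
  expect_gt(mean(fx$n_ips[sc]), mean(fx$n_ips[!sc]))
})

test_that("empty logs and unknown accounts raise errors", {
  expect_error(extract_features_all(empty_event_log()), "empty")
  ev <- make_events(data.frame(action = "book"))
  expect_error(extract_features(ev, "ghost"), "no events")
})
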