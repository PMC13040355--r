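# Shared fixtures: tiny hand-built event logs and synthetic Gaussian design
# matrices used across the unit tests. Everything is generated in code.

hours_ts <- function(h) {
  as.POSIXct("2020-06-01 00:00:00", tz = "UTC") + h * 3600
}

# Build a minimal schema-valid event log by hand. `spec_rows` is a data frame
# with at least account_id, action and timestamp; remaining schema columns are
# filled with defaults.
make_events <- function(spec_rows) {
  n <- nrow(spec_rows)
  defaults <- tibble::tibble(
    event_id = sprintf("e%04d", seq_len(n)),
    account_id = "a1",
    device_id = "d1",
    ip = "ip1",
    card_id = "c1",
    timestamp = hours_ts(seq_len(n)),
    department = "internal_medicine",
    channel = "online",
    action = "book",
    op_duration_s = 20,
    session_id = "s1",
    ref_event_id = NA_character_)
  for (col in names(spec_rows)) defaults[[col]] <- spec_rows[[col]]
  defaults
}

# A small but fully featured simulation configuration (fast to generate).
small_config <- function(seed = 1, ...) {
  sim_config(n_accounts = 300, arrival_rate_per_day = 6,
             period_start = as.Date("2020-01-01"),
             intervention_date = as.Date("2020-07-01"),
             period_end = as.Date("2020-12-31"),
             seed = seed, ...)
}

# Synthetic design matrix: two Gaussian classes in the full feature space,
# abnormal centered at `mu_pos` (recycled over the 13 columns), normal at
# `mu_neg`, both with unit variance. Already "standardized" (center 0/scale 1).
make_gauss_dm <- function(n_pos, n_neg, mu_pos, mu_neg = 0, sd = 1,
                          seed = 1) {
  set.seed(seed)
  feats <- feature_names()
  d <- length(feats)
  X <- rbind(
    matrix(rnorm(n_pos * d, mean = rep(mu_pos, length.out = d), sd = sd),
           nrow = n_pos, byrow = TRUE),
    matrix(rnorm(n_neg * d, mean = rep(mu_neg, length.out = d), sd = sd),
           nrow = n_neg, byrow = TRUE))
  dm <- tibble::as_tibble(as.data.frame(X))
  names(dm) <- feats
  dm$account_id <- sprintf("acct%05d", seq_len(n_pos + n_neg))
  dm$label <- c(rep("abnormal", n_pos), rep("normal", n_neg))
  structure(dm,
            center = stats::setNames(rep(0, d), feats),
            scale = stats::setNames(rep(1, d), feats),
            class = c("design_matrix", class(tibble::tibble())))
}

# Quadratic-time oracle for the sliding-window maximum: enumerate windows
# anchored at every event and count membership directly.
brute_max_in_window <- function(times, width_s) {
  if (length(times) == 0) return(0L)
  max(vapply(times, function(t0) {
    sum(times >= t0 & times < t0 + width_s)
  }, numeric(1)))
}
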