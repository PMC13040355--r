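#' Write a registration event log to disk
#'
#' JSONL is the canonical on-disk dialect: the first line is a JSON header
#' carrying the event count and the generating seed, followed by one event
#' object per line with ISO-8601 UTC timestamps at millisecond resolution.
#' CSV is a convenience export with the documented column order of
#' [simulate_events()] and no metadata header.
#'
#' @param events event log tibble.
#' @param path output file; format inferred from the extension (`.jsonl` /
#'   `.csv`) unless `format` is given.
#' @param format `"jsonl"` or `"csv"`.
#' @param seed optional integer recorded in the JSONL header.
#' @return invisibly, `path`.
#' @export
write_event_log <- function(events, path, format = NULL, seed = NULL) {
  format <- format %||% infer_format(path)
  out <- events
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  if (format == "jsonl") {
    header <- jsonlite::toJSON(
      list(type = "header", n_events = nrow(events),
           seed = seed %||% NA_integer_, schema = event_log_columns()),
      auto_unbox = TRUE, na = "null")
    lines <- vapply(seq_len(nrow(out)), function(i) {
      jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE, na = "null")
    }, character(1))
    writeLines(c(header, lines), path)
  } else {
    utils::write.csv(as.data.frame(out)[, event_log_columns()], path,
                     row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a registration event log
#'
#' Performs a lossless round-trip of [write_event_log()] output and validates
#' every row against the event schema; schema-invalid rows abort with their
#' line number.
#'
#' @param path input file (`.jsonl` or `.csv`).
#' @param format `"jsonl"` or `"csv"` (inferred from the extension).
#' @return event log tibble; an empty file yields an empty log.
#' @export
read_event_log <- function(path, format = NULL) {
  format <- format %||% infer_format(path)
  if (format == "jsonl") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) return(empty_event_log())
    first <- jsonlite::fromJSON(lines[1])
    offset <- if (identical(first$type, "header")) 1L else 0L
    body <- lines[seq_len(length(lines) - offset) + offset]
    if (length(body) == 0) return(empty_event_log())
    rows <- lapply(seq_along(body), function(i) {
      rec <- jsonlite::fromJSON(body[i])
      if (is.null(rec$account_id) || is.na(rec$account_id)) {
        abort(sprintf("line %d: missing account_id", i + offset))
      }
      rec$ref_event_id <- rec$ref_event_id %||% NA_character_
      as_tibble(rec[event_log_columns()])
    })
    df <- bind_rows(rows)
  } else {
    if (file.size(path) == 0) return(empty_event_log())
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    if (nrow(df) == 0) return(empty_event_log())
    missing_acct <- which(is.na(df$account_id) | df$account_id == "")
    if (length(missing_acct) > 0) {
      abort(sprintf("line %d: missing account_id", missing_acct[1] + 1L))
    }
    df <- as_tibble(df)
    df$op_duration_s <- as.numeric(df$op_duration_s)
    df$ref_event_id[df$ref_event_id == ""] <- NA_character_
  }
  df$timestamp <- parse_iso_ts(as.character(df$timestamp))
  df$op_duration_s <- as.numeric(df$op_duration_s)
  df <- df[, event_log_columns()]
  validate_event_log(df)
  df
}

event_log_columns <- function() {
  c("event_id", "account_id", "device_id", "ip", "card_id", "timestamp",
    "department", "channel", "action", "op_duration_s", "session_id",
    "ref_event_id")
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) "jsonl"
  else if (ext == "csv") "csv"
  else abort(sprintf("cannot infer event-log format from '%s'", path))
}

parse_iso_ts <- function(x) {
  old <- options(digits.secs = 3); on.exit(options(old))
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  if (anyNA(out) && !anyNA(x)) abort("unparseable ISO-8601 timestamp")
  out
}

#' Read and validate a pipeline run configuration
#'
#' The YAML file may contain the blocks `simulation` (fields of
#' [sim_config()]), `model` (`prior`, `threshold`, `lambda_reg`, `gain`),
#' `policy` (fields of [intervention_policy()]), `queue` (`lambda`, `mu`,
#' `servers`, `horizon`), `evaluation` (`bootstrap_B`) and a global `seed`.
#' Unknown keys — at the top level or inside a block — are rejected.
#'
#' @param path YAML file.
#' @return list with validated `simulation`, `model`, `policy`, `queue`,
#'   `evaluation`, `seed` components.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("simulation", "model", "policy", "queue", "evaluation", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "scalpguard_config_error")
  }
  check_block <- function(block, fn, name) {
    block <- block %||% list()
    bad <- setdiff(names(block), names(formals(fn)))
    if (length(bad) > 0) {
      abort(sprintf("unknown key(s) in '%s' block: %s", name,
                    paste(bad, collapse = ", ")),
            class = "scalpguard_config_error")
    }
    block
  }
  sim_block <- check_block(raw$simulation, sim_config, "simulation")
  for (d in intersect(c("period_start", "intervention_date", "period_end"),
                      names(sim_block))) {
    sim_block[[d]] <- as.Date(sim_block[[d]])
  }
  pol_block <- check_block(raw$policy, intervention_policy, "policy")
  model_def <- list(prior = 0.05, threshold = 0.75, lambda_reg = 0.1, gain = 2)
  model <- utils::modifyList(model_def, check_block_names(
    raw$model, names(model_def), "model"))
  queue_def <- list(lambda = 8, mu = 1, servers = 10, horizon = 2000)
  queue <- utils::modifyList(queue_def, check_block_names(
    raw$queue, names(queue_def), "queue"))
  eval_def <- list(bootstrap_B = 200)
  evaluation <- utils::modifyList(eval_def, check_block_names(
    raw$evaluation, names(eval_def), "evaluation"))
  seed <- raw$seed %||% sim_block$seed %||% 1L
  sim_block$seed <- as.integer(seed)
  list(simulation = do.call(sim_config, sim_block),
       model = model,
       policy = do.call(intervention_policy, pol_block),
       queue = queue, evaluation = evaluation, seed = as.integer(seed))
}

check_block_names <- function(block, known, name) {
  block <- block %||% list()
  bad <- setdiff(names(block), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown key(s) in '%s' block: %s", name,
                  paste(bad, collapse = ", ")),
          class = "scalpguard_config_error")
  }
  block
}

#' Run the full pipeline from a configuration
#'
#' simulate -> label -> features -> fit -> deploy -> evaluate, via
#' [run_experiment()], returning a serializable run report.
#'
#' @param config list from [read_run_config()], or a path to a YAML file.
#' @param seed optional integer overriding the configured seed.
#' @return object of class `run_report`: configuration echo, seed, per-stage
#'   record counts, the per-period outcome table and the flattened evaluation
#'   results, and the package version.
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- seed %||% config$seed
  ex <- run_experiment(config$simulation, policy = config$policy,
                       model = config$model, queue = config$queue,
                       eval_config = config$evaluation, seed = seed)
  ev <- ex$evaluation
  report <- list(
    seed = seed,
    config = list(
      simulation = config$simulation[setdiff(names(config$simulation),
                                             c("departments", "group_attrs"))],
      model = config$model, queue = config$queue,
      evaluation = config$evaluation),
    counts = list(accounts = nrow(ex$scores) + 0,
                  scored_accounts = nrow(ex$scores),
                  flagged_accounts = sum(ex$scores$decision == "flag"),
                  bookings = sum(ex$outcome$bookings),
                  blocked_bookings = sum(ex$outcome$blocked_bookings)),
    outcome = as.data.frame(ex$outcome),
    evaluation = list(
      completion_chisq = as.data.frame(ev$completion_chisq),
      completion_rr = as.data.frame(ev$completion_rr),
      completion_change_pp = ev$completion_change_pp,
      confusion = as.data.frame(ev$confusion),
      fairness_age_gap = ev$fairness_age$gap,
      fairness_socio_gap = ev$fairness_socio$gap,
      its = if (!is.null(ev$its)) as.data.frame(tidy(ev$its)) else NULL,
      bootstrap_completion = as.data.frame(ev$bootstrap_completion),
      flagged_booking_drop_pct = ev$flagged_booking_drop_pct,
      wrongly_flagged_legit_pct = ev$wrongly_flagged_legit_pct),
    version = as.character(utils::packageVersion("scalpguard")))
  structure(report, class = "run_report")
}

#' Serialize / reload a run report
#'
#' @param report a `run_report`.
#' @param path JSON output file.
#' @return `write_run_report()` returns `path` invisibly;
#'   [read_run_report()] returns the reloaded `run_report`.
#' @export
write_run_report <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  stripped <- unclass(report)
  stripped$config$simulation <- lapply(stripped$config$simulation, function(v) {
    if (inherits(v, "Date")) as.character(v) else v
  })
  jsonlite::write_json(stripped, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_report
#' @export
read_run_report <- function(path) {
  structure(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, scalpguard %s\n", x$seed, x$version))
  cat(sprintf("  %d bookings (%d blocked), %d accounts flagged\n",
              x$counts$bookings, x$counts$blocked_bookings,
              x$counts$flagged_accounts))
  cat(sprintf("  completion change %+.1f pp; flagged-booking drop %.1f%%\n",
              x$evaluation$completion_change_pp,
              x$evaluation$flagged_booking_drop_pct))
  invisible(x)
}
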