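#' Bundled annual registration summary tables
#'
#' Published annual summaries from the hospital registration study the
#' package's defaults are calibrated against, shipped as plain-CSV fixtures:
#' annual outpatient and appointment volumes (2020--2023), annual appointment
#' completion/no-show rates (2019--2022, intervention in January 2021),
#' registration-channel mix by year, and the reported validation metrics of
#' the behavioural recognition model. These are inputs for the worked
#' reproduction of the study's headline numbers (appointment rates, relative
#' risk, completion improvement, F1).
#'
#' @param table one of `"volume"`, `"completion"`, `"channel"`, `"model"`.
#' @return a tibble.
#' @examples
#' registration_summary("volume")
#' @export
registration_summary <- function(table = c("volume", "completion", "channel",
                                           "model")) {
  table <- match.arg(table)
  file <- switch(table,
                 volume = "annual_registration_volume.csv",
                 completion = "annual_completion_rates.csv",
                 channel = "channel_mix_by_year.csv",
                 model = "model_validation_metrics.csv")
  path <- system.file("extdata", file, package = "scalpguard")
  if (path == "") abort(sprintf("bundled table '%s' not found", file))
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Appointment registration rates from annual volumes
#'
#' @param volumes tibble with `outpatient_volume` and `appointment_volume`
#'   (default the bundled `"volume"` table).
#' @return the input with an `appointment_rate_pct` column
#'   (`100 * appointment / outpatient`) plus a final pooled row holding the
#'   mean volumes and the rate implied by them.
#' @examples
#' appointment_rates()
#' @export
appointment_rates <- function(volumes = registration_summary("volume")) {
  out <- volumes |>
    mutate(appointment_rate_pct =
             100 * .data$appointment_volume / .data$outpatient_volume)
  mean_row <- tibble(year = NA_integer_,
                     outpatient_volume = mean(out$outpatient_volume),
                     appointment_volume = mean(out$appointment_volume),
                     appointment_rate_pct = 100 * mean(out$appointment_volume) /
                       mean(out$outpatient_volume))
  bind_rows(out, mean_row)
}
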