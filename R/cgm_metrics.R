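# Time-range glycometrics from 5-minute interstitial glucose traces.
#
# A trace is a long-format data frame with columns subject_id, timestamp
# (POSIXct, nominal 5-min grid) and glucose_mg_dl.  Devices report glucose
# within 40-400 mg/dL at 288 samples per full wear day.

SAMPLES_PER_DAY <- 288L
GLUCOSE_RANGE <- c(40, 400)

#' Read / write long-format CGM traces
#'
#' The on-disk format is a headered CSV with columns `subject_id`,
#' `timestamp` (ISO-8601, UTC) and `glucose_mg_dl`.  On read, raw values
#' outside the device reporting range 40-400 mg/dL are clamped to it with a
#' warning, mirroring sensor behaviour.
#'
#' @param path File path.
#' @param clamp Clamp out-of-range glucose values on read (default `TRUE`).
#' @return A tibble with the three trace columns.
#' @export
read_cgm_csv <- function(path, clamp = TRUE) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           timestamp = readr::col_datetime(),
                           glucose_mg_dl = readr::col_double()
                         ))
  validate_cgm(out, clamp = clamp)
}

#' @rdname read_cgm_csv
#' @param trace A CGM trace data frame.
#' @export
write_cgm_csv <- function(trace, path) {
  readr::write_csv(trace, path)
  invisible(path)
}

#' Validate (and clamp) a CGM trace
#'
#' Checks the schema, that timestamps are strictly increasing within each
#' subject, and that glucose values lie inside the device range 40-400 mg/dL
#' (clamped with a warning otherwise).
#'
#' @inheritParams write_cgm_csv
#' @param clamp Clamp out-of-range values rather than erroring.
#' @return The validated trace as a tibble.
#' @export
validate_cgm <- function(trace, clamp = TRUE) {
  stopifnot(is.data.frame(trace))
  needed <- c("subject_id", "timestamp", "glucose_mg_dl")
  missing_cols <- setdiff(needed, names(trace))
  if (length(missing_cols)) {
    abort(paste0("CGM trace is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(trace) == 0L) abort("CGM trace is empty")
  if (anyNA(trace$glucose_mg_dl)) abort("CGM trace contains missing glucose values")
  trace <- tibble::as_tibble(trace)
  bad <- trace |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::filter(dplyr::row_number() > 1L & diff_nonpos(.data$timestamp)) |>
    dplyr::ungroup()
  if (nrow(bad)) {
    abort(paste0("timestamps not strictly increasing for subject ",
                 bad$subject_id[1L], " at row ", bad$.row[1L]))
  }
  out_of_range <- trace$glucose_mg_dl < GLUCOSE_RANGE[1] |
    trace$glucose_mg_dl > GLUCOSE_RANGE[2]
  if (any(out_of_range, na.rm = TRUE)) {
    if (!clamp) abort("glucose values outside the 40-400 mg/dL device range")
    warn(paste0(sum(out_of_range, na.rm = TRUE),
                " glucose value(s) outside 40-400 mg/dL clamped to the device range"))
    trace$glucose_mg_dl <- clamp(trace$glucose_mg_dl, GLUCOSE_RANGE[1], GLUCOSE_RANGE[2])
  }
  trace
}

diff_nonpos <- function(ts) {
  d <- c(1, diff(as.numeric(ts)))
  d <= 0
}

#' Summarize CGM wear time
#'
#' A calendar day counts as *complete* when it holds at least
#' `completeness_fraction` of the nominal 288 five-minute samples
#' (default 0.8, i.e. at least 231 samples).  Subjects are eligible for
#' analysis when they contribute at least `min_days` complete days
#' (default 2).
#'
#' @param trace A long-format CGM trace (one or more subjects).
#' @param completeness_fraction Fraction of 288 samples a calendar day must
#'   reach to count as complete; in (0, 1].
#' @param min_days Minimum number of complete days for eligibility.
#' @return A tibble with one row per subject: `complete_days`,
#'   `total_valid_samples` (samples on complete days) and `eligible`.
#' @export
wear_summary <- function(trace, completeness_fraction = 0.8, min_days = 2L) {
  stopifnot(completeness_fraction > 0, completeness_fraction <= 1)
  trace <- validate_cgm(trace)
  threshold <- ceiling(completeness_fraction * SAMPLES_PER_DAY)
  trace |>
    dplyr::mutate(day = as.Date(.data$timestamp)) |>
    dplyr::count(.data$subject_id, .data$day, name = "n_samples") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      complete_days = sum(.data$n_samples >= threshold),
      total_valid_samples = sum(.data$n_samples[.data$n_samples >= threshold]),
      .groups = "drop"
    ) |>
    dplyr::mutate(eligible = .data$complete_days >= min_days)
}

#' Retain only complete wear days of a CGM trace
#'
#' Applies the completeness rule of [wear_summary()] and drops all samples
#' falling on incomplete calendar days.  Metrics downstream are computed on
#' complete days only.
#'
#' @inheritParams wear_summary
#' @return The filtered trace, with the per-subject wear summary attached as
#'   attribute `"wear"` (also retrievable by calling [wear_summary()]).
#' @export
filter_complete_days <- function(trace, completeness_fraction = 0.8, min_days = 2L) {
  stopifnot(completeness_fraction > 0, completeness_fraction <= 1)
  trace <- validate_cgm(trace)
  threshold <- ceiling(completeness_fraction * SAMPLES_PER_DAY)
  wear <- wear_summary(trace, completeness_fraction, min_days)
  out <- trace |>
    dplyr::mutate(day = as.Date(.data$timestamp)) |>
    dplyr::group_by(.data$subject_id, .data$day) |>
    dplyr::filter(dplyr::n() >= threshold) |>
    dplyr::ungroup() |>
    dplyr::select(-"day")
  attr(out, "wear") <- wear
  out
}

# fractions of samples in [70,140], >140, <70; boundary values are in range
range_fractions <- function(glucose) {
  n <- length(glucose)
  tar <- sum(glucose > 140) / n
  tbr <- sum(glucose < 70) / n
  c(tir = 1 - tar - tbr, tar = tar, tbr = tbr)
}

#' Time-in-range metrics (TIR / TAR / TBR)
#'
#' Computes, per subject, the percentage of glucose samples in the target
#' range 70-140 mg/dL (TIR), above 140 mg/dL (TAR) and below 70 mg/dL (TBR).
#' The boundary values 70 and 140 belong to the in-range interval; TAR and
#' TBR are strict inequalities.  Every retained sample is weighted equally,
#' so on the uniform 5-minute grid sample proportions equal time proportions.
#' The three percentages always sum to 100.
#'
#' @param trace A long-format CGM trace, normally already restricted to
#'   complete days with [filter_complete_days()].
#' @return A tibble with one row per subject: `tir_pct`, `tar_pct`,
#'   `tbr_pct` and `n_samples_used`.
#' @export
compute_time_in_ranges <- function(trace) {
  trace <- validate_cgm(trace)
  trace |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_samples_used = dplyr::n(),
      tar_pct = 100 * sum(.data$glucose_mg_dl > 140) / .data$n_samples_used,
      tbr_pct = 100 * sum(.data$glucose_mg_dl < 70) / .data$n_samples_used,
      tir_pct = 100 - .data$tar_pct - .data$tbr_pct,
      .groups = "drop"
    ) |>
    dplyr::select("subject_id", "tir_pct", "tar_pct", "tbr_pct", "n_samples_used")
}
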