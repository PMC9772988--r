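# shared fixtures, all generated in code

# a regular 5-min trace for one subject: `days` full days of given values
make_trace <- function(values, subject_id = "S1", start = "2012-06-01") {
  n <- length(values)
  tibble::tibble(
    subject_id = subject_id,
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1L) * 300,
    glucose_mg_dl = values
  )
}

# trace with a chosen number of samples on each calendar day
make_partial_trace <- function(samples_per_day, subject_id = "S1",
                               value = 100, start = "2012-06-01") {
  start <- as.POSIXct(start, tz = "UTC")
  rows <- purrr::imap_dfr(samples_per_day, function(k, d) {
    tibble::tibble(
      subject_id = subject_id,
      timestamp = start + (d - 1L) * 86400 + (seq_len(k) - 1L) * 300,
      glucose_mg_dl = value
    )
  })
  rows
}

# small desk-scale study configuration
small_config <- function(seed = 42L, n = 60L, n_prog = 6L) {
  cohort_config(n_subjects = n, n_progressors = n_prog, seed = seed)
}

# glucodensity from raw draws (clamped into the device range)
density_of <- function(x, bandwidth = NULL) {
  estimate_glucodensity(pmin(pmax(x, 40), 400), bandwidth = bandwidth)
}

# probability mass of a glucodensity strictly above a threshold (trapezoid)
trapz_mass_above <- function(d, threshold) {
  sel <- d$grid >= threshold
  x <- d$grid[sel]
  y <- d$density[sel]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# brute-force AUC oracle: pairwise case/control comparison, ties one half
pair_count_auc <- function(scores, outcomes) {
  cases <- scores[as.logical(outcomes)]
  controls <- scores[!as.logical(outcomes)]
  cmp <- outer(cases, controls, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
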