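# Synthetic cohort and CGM trace generator.
#
# Emulates a population-based CGM study of adults without diabetes followed
# for incident type 2 diabetes over 5 years: group-conditional baseline
# covariates, ATP-III component prevalences, wear-time distribution, and
# 5-minute glucose traces whose time-above-range calibration is tied to a
# latent per-subject TAR propensity.

#' Trace-model settings for the CGM generator
#'
#' The simulated interstitial glucose signal is
#' `basal + circadian + amplitude x excursion_shape + AR(1) noise`, clamped
#' to the 40-400 mg/dL device range on a 5-minute grid (288 samples/day).
#' The basal level is anchored to HbA1c through the linear estimated-average
#' -glucose relation `eAG = 28.7 x HbA1c - 46.7` (mg/dL); the excursion
#' shape holds three Gaussian meal bumps plus a sustained daytime elevation;
#' the per-subject amplitude is solved so the expected fraction of time
#' above 140 mg/dL equals the subject's TAR propensity.
#'
#' @param basal Fixed basal glucose in mg/dL; overrides the HbA1c anchor
#'   when non-`NULL` (used mainly for degenerate test traces).
#' @param basal_intercept,basal_slope Basal anchor
#'   `basal_intercept + basal_slope x (eAG - 100)`: the basal level tracks
#'   the estimated average glucose only partially because meal excursions
#'   supply the remainder of the daily average.
#' @param circadian_amplitude,circadian_peak_hour Cosine circadian component
#'   (mg/dL, hour of day).
#' @param meal_times,meal_sd_hours,meal_rel_amplitude Meal excursion centres
#'   (hours), spread, and relative sizes.
#' @param meal_jitter_sd_hours Day-to-day jitter of meal times (hours).
#' @param sustained_fraction Sustained (all-day) share of the excursion
#'   shape, letting high TAR propensities raise the daytime baseline too.
#' @param noise_sd,ar1_phi Marginal SD (mg/dL) and lag-1 autocorrelation of
#'   the stationary AR(1) sensor/physiology noise.
#' @param start_date Calendar date of the first monitoring midnight.
#' @return A list of class `cgm_trace_config`.
#' @export
trace_config <- function(basal = NULL, basal_intercept = 95,
                         basal_slope = 0.5,
                         circadian_amplitude = 5, circadian_peak_hour = 16,
                         meal_times = c(8, 13.5, 20.5),
                         meal_sd_hours = 0.75,
                         meal_rel_amplitude = c(1, 0.9, 0.85),
                         meal_jitter_sd_hours = 0.3,
                         sustained_fraction = 0.15,
                         noise_sd = 8, ar1_phi = 0.7,
                         start_date = "2012-06-01") {
  stopifnot(noise_sd >= 0, ar1_phi >= 0, ar1_phi < 1,
            length(meal_times) == length(meal_rel_amplitude),
            meal_sd_hours > 0, sustained_fraction >= 0)
  structure(list(basal = basal, basal_intercept = basal_intercept,
                 basal_slope = basal_slope,
                 circadian_amplitude = circadian_amplitude,
                 circadian_peak_hour = circadian_peak_hour,
                 meal_times = meal_times, meal_sd_hours = meal_sd_hours,
                 meal_rel_amplitude = meal_rel_amplitude,
                 meal_jitter_sd_hours = meal_jitter_sd_hours,
                 sustained_fraction = sustained_fraction,
                 noise_sd = noise_sd, ar1_phi = ar1_phi,
                 start_date = start_date),
            class = "cgm_trace_config")
}

default_group_moments <- function() {
  list(
    non_progressor = list(age = c(46.4, 13.8), bmi = c(27.6, 4.9),
                          fpg = c(87, 10), hba1c = c(5.3, 0.3),
                          homa_ir = c(2.55, 1.69)),
    progressor = list(age = c(54.8, 10.0), bmi = c(33.2, 4.8),
                      fpg = c(105, 12), hba1c = c(5.8, 0.7),
                      homa_ir = c(5.32, 3.31))
  )
}

default_group_prevalences <- function() {
  list(
    non_progressor = c(male = 168 / 477, family_history = 241 / 477,
                       abdominal_obesity = 171 / 477,
                       hypertriglyceridaemia = 78 / 477,
                       low_hdl = 79 / 477, high_bp = 174 / 477),
    progressor = c(male = 7 / 22, family_history = 14 / 22,
                   abdominal_obesity = 19 / 22,
                   hypertriglyceridaemia = 6 / 22,
                   low_hdl = 6 / 22, high_bp = 17 / 22)
  )
}

default_tar_distribution <- function() {
  list(non_progressor = c(median = 1.9, q1 = 0.4, q3 = 5.1),
       progressor = c(median = 7.8, q1 = 4.5, q3 = 20.0))
}

default_wear_day_distribution <- function() {
  # pooled wear-time frequencies over the analysed cohort (2-6 complete days)
  setNames(c(9, 16, 29, 427, 18) / 499, 2:6)
}

default_causal_coefficients <- function() {
  c(age = log(1.03), sex_male = log(1.2), family_history = log(1.8),
    bmi = log(1.10), hba1c = log(3.5), tar_pct = log(1.06))
}

default_correlation_spec <- function() {
  # Within-group Spearman rank correlations on (hba1c, fpg, tar, bmi).
  # Moderate values keep TAR informative conditional on HbA1c, matching the
  # adjusted-model structure of the emulated study; the whole-cohort
  # marginal correlation additionally picks up the group separation.
  c(hba1c_fpg = 0.50, hba1c_tar = 0.55, fpg_tar = 0.50,
    bmi_hba1c = 0.25, bmi_fpg = 0.25, bmi_tar = 0.25)
}

# Bounds for the truncated marginals.  Enrolment excludes *diagnosed*
# baseline diabetes; because an ADA diagnosis needs two abnormal samples, a
# single mildly abnormal baseline value (HbA1c in [6.5, 7.5), FPG in
# [126, 140)) is still compatible with enrolment as a non-diabetic subject
# (and the printed progressor moments require such mass).  The caps keep
# every profile short of unequivocal hyperglycaemia.
marginal_bounds <- function() {
  list(age = c(18, 100), bmi = c(10, 80), fpg = c(40, 140), hba1c = c(3, 7.5))
}

#' Configuration of the synthetic cohort generator
#'
#' Packages the study conditions the generator reproduces: group-conditional
#' moments of the baseline covariates, component prevalences, group TAR
#' (time-above-range) median/IQR targets, the wear-day distribution, rank
#' correlations of the latent copula, causal log-odds coefficients, and the
#' CGM trace model.  Defaults encode the reported characteristics of a
#' 499-subject adult cohort with 22 five-year progressors to type 2
#' diabetes.
#'
#' Continuous covariates use truncated normal marginals (lognormal for
#' HOMA-IR; truncated lognormal fitted to median/IQR for TAR propensity)
#' whose underlying parameters are moment-matched at configuration time so
#' the *truncated* distributions hit the requested moments; the achievable
#' moments are stored in `$fitted` (for one over-constrained target --
#' progressor HbA1c under the no-baseline-diabetes cap -- the closest family
#' member is used).  Joint structure on (HbA1c, FPG, TAR propensity, BMI)
#' comes from a Gaussian copula with the requested rank correlations.
#'
#' @param n_subjects Cohort size (default 499).
#' @param n_progressors Number of incident-diabetes subjects in
#'   matched-moments mode (default 22); must be smaller than `n_subjects`.
#' @param group_moments Per-group list of `c(mean, sd)` for `age`, `bmi`,
#'   `fpg`, `hba1c`, `homa_ir`.
#' @param group_prevalences Per-group named proportions for `male`,
#'   `family_history`, `abdominal_obesity`, `hypertriglyceridaemia`,
#'   `low_hdl`, `high_bp` (the ATP-III hyperglycaemia component is derived
#'   from the drawn FPG for internal consistency).
#' @param tar_distribution Per-group `c(median, q1, q3)` targets for TAR %.
#' @param wear_day_distribution Probabilities over 2-6 complete wear days;
#'   must sum to one.
#' @param causal_coefficients Named log-odds used by
#'   [assign_outcomes_causal()]; includes the per-percentage-point TAR
#'   effect `tar_pct`.
#' @param correlation_spec Named Spearman correlations among
#'   (HbA1c, FPG, TAR propensity, BMI).
#' @param trace A [trace_config()].
#' @param seed Integer seed (mandatory here or at generation time).
#' @return A validated list of class `cgm_cohort_config` with fitted
#'   marginal parameters under `$fitted`.
#' @export
cohort_config <- function(n_subjects = 499L, n_progressors = 22L,
                          group_moments = default_group_moments(),
                          group_prevalences = default_group_prevalences(),
                          tar_distribution = default_tar_distribution(),
                          wear_day_distribution = default_wear_day_distribution(),
                          causal_coefficients = default_causal_coefficients(),
                          correlation_spec = default_correlation_spec(),
                          trace = trace_config(),
                          seed = NULL) {
  n_subjects <- as.integer(n_subjects)
  n_progressors <- as.integer(n_progressors)
  if (n_subjects < 2L || n_progressors < 0L || n_progressors >= n_subjects) {
    abort("configuration error: need 0 <= n_progressors < n_subjects")
  }
  groups <- c("non_progressor", "progressor")
  if (!all(groups %in% names(group_moments)) ||
      !all(groups %in% names(group_prevalences)) ||
      !all(groups %in% names(tar_distribution))) {
    abort("configuration error: per-group settings need `non_progressor` and `progressor` entries")
  }
  for (g in groups) {
    sds <- vapply(group_moments[[g]], `[`, numeric(1), 2L)
    if (any(sds <= 0)) abort("configuration error: all SDs must be positive")
    pr <- group_prevalences[[g]]
    if (any(pr < 0 | pr > 1)) abort("configuration error: prevalences must lie in [0, 1]")
    td <- tar_distribution[[g]]
    if (!(td["q1"] > 0 && td["q1"] < td["median"] && td["median"] < td["q3"])) {
      abort("configuration error: TAR targets need 0 < q1 < median < q3")
    }
  }
  if (any(wear_day_distribution < 0) ||
      abs(sum(wear_day_distribution) - 1) > 1e-8) {
    abort("configuration error: wear-day probabilities must be nonnegative and sum to 1")
  }
  bounds <- marginal_bounds()
  fitted <- lapply(setNames(groups, groups), function(g) {
    gm <- group_moments[[g]]
    marg <- lapply(setNames(names(bounds), names(bounds)), function(v) {
      fit_truncnorm(gm[[v]][1L], gm[[v]][2L], bounds[[v]][1L], bounds[[v]][2L])
    })
    marg$homa_ir <- lognormal_from_moments(gm$homa_ir[1L], gm$homa_ir[2L])
    td <- tar_distribution[[g]]
    marg$tar <- fit_tar_splice(td[["median"]], td[["q1"]], td[["q3"]])
    marg
  })
  cs <- correlation_spec
  R <- diag(4)
  dimnames(R) <- list(c("hba1c", "fpg", "tar", "bmi"),
                      c("hba1c", "fpg", "tar", "bmi"))
  R["hba1c", "fpg"] <- R["fpg", "hba1c"] <- spearman_to_pearson(cs[["hba1c_fpg"]])
  R["hba1c", "tar"] <- R["tar", "hba1c"] <- spearman_to_pearson(cs[["hba1c_tar"]])
  R["fpg", "tar"] <- R["tar", "fpg"] <- spearman_to_pearson(cs[["fpg_tar"]])
  R["bmi", "hba1c"] <- R["hba1c", "bmi"] <- spearman_to_pearson(cs[["bmi_hba1c"]])
  R["bmi", "fpg"] <- R["fpg", "bmi"] <- spearman_to_pearson(cs[["bmi_fpg"]])
  R["bmi", "tar"] <- R["tar", "bmi"] <- spearman_to_pearson(cs[["bmi_tar"]])
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) abort("configuration error: correlation_spec is not positive definite")
  structure(
    list(n_subjects = n_subjects, n_progressors = n_progressors,
         group_moments = group_moments, group_prevalences = group_prevalences,
         tar_distribution = tar_distribution,
         wear_day_distribution = wear_day_distribution,
         causal_coefficients = causal_coefficients,
         correlation_spec = correlation_spec,
         copula_R = R, fitted = fitted, trace = trace, seed = seed),
    class = "cgm_cohort_config"
  )
}

#' @export
print.cgm_cohort_config <- function(x, ...) {
  cat("<cgm_cohort_config>\n")
  cat(sprintf("  %d subjects, %d progressors (matched-moments mode)\n",
              x$n_subjects, x$n_progressors))
  cat(sprintf("  TAR medians: %.1f%% / %.1f%% (non-progressor / progressor)\n",
              x$tar_distribution$non_progressor[["median"]],
              x$tar_distribution$progressor[["median"]]))
  cat(sprintf("  seed: %s\n", if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Generate a synthetic cohort (matched-moments mode)
#'
#' Draws `n_subjects` baseline profiles of which exactly `n_progressors`
#' carry a positive 5-year outcome, each group's covariates coming from its
#' configured truncated marginals coupled through the Gaussian copula.
#' Fasting insulin is back-computed from the drawn HOMA-IR and FPG so the
#' three quantities are mutually consistent; no profile meets the ADA
#' diabetes criteria at baseline.  A latent `tar_propensity_pct` column
#' carries each subject's target expected time above range, consumed by the
#' trace generator.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed` (one of the two is
#'   mandatory).
#' @return A tibble with one row per subject (see package README for the
#'   column dictionary), of class `cgm_cohort`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cgm_cohort_config"))
  if (is.null(seed)) abort("a seed is mandatory (in the config or as an argument)")
  with_seed(seed, {
    n <- config$n_subjects
    outcome <- rep(FALSE, n)
    outcome[sample.int(n, config$n_progressors)] <- TRUE
    rows <- vector("list", 2L)
    names(rows) <- c("non_progressor", "progressor")
    for (g in names(rows)) {
      idx <- if (g == "progressor") which(outcome) else which(!outcome)
      rows[[g]] <- draw_group(length(idx), g, config)
      rows[[g]]$.idx <- idx
    }
    cohort <- dplyr::bind_rows(rows)
    cohort <- cohort[order(cohort$.idx), , drop = FALSE]
    cohort$.idx <- NULL
    cohort <- tibble::as_tibble(cohort)
    cohort <- dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("S%04d", seq_len(n))), cohort
    )
    cohort$outcome_t2d_5y <- outcome
    cohort$wear_days <- sample(as.integer(names(config$wear_day_distribution)),
                               n, replace = TRUE,
                               prob = config$wear_day_distribution)
    # nobody may satisfy the *confirmed* ADA criteria at baseline
    stopifnot(!any(ada_diabetes(cohort$fpg, cohort$hba1c,
                                second_sample_abnormal = FALSE,
                                unequivocal_hyperglycaemia = FALSE)),
              all(cohort$fpg < 140), all(cohort$hba1c < 7.5))
    class(cohort) <- c("cgm_cohort", class(cohort))
    cohort
  })
}

draw_group <- function(n_g, g, config) {
  fitted <- config$fitted[[g]]
  prev <- config$group_prevalences[[g]]
  if (n_g == 0L) {
    return(tibble::tibble(age = numeric(), sex = character(),
                          family_history_dm = logical(), bmi = numeric(),
                          waist = numeric(), fpg = numeric(), hba1c = numeric(),
                          fasting_insulin = numeric(), homa_ir = numeric(),
                          triglycerides = numeric(), hdl = numeric(),
                          sbp = numeric(), dbp = numeric(),
                          antihypertensive_use = logical(),
                          tar_propensity_pct = numeric()))
  }
  u <- copula_uniform(n_g, config$copula_R)
  qt <- function(fit, p) qtruncnorm(p, fit$mean, fit$sd, fit$lower, fit$upper)
  hba1c <- qt(fitted$hba1c, u[, "hba1c"])
  fpg <- qt(fitted$fpg, u[, "fpg"])
  tar <- qtar_splice(u[, "tar"], fitted$tar)
  bmi <- qt(fitted$bmi, u[, "bmi"])
  age <- qt(fitted$age, runif(n_g))
  homa <- qlnorm(runif(n_g), fitted$homa_ir$meanlog, fitted$homa_ir$sdlog)
  male <- runif(n_g) < prev[["male"]]
  famhx <- runif(n_g) < prev[["family_history"]]

  # ATP-III component values drawn conditionally on their prevalence flags,
  # so the flag recomputed from the value always agrees with the draw
  waist_cut <- ifelse(male, 102, 88)
  waist_mean <- ifelse(male, 97, 87)
  ab_ob <- runif(n_g) < prev[["abdominal_obesity"]]
  waist <- cond_truncnorm(runif(n_g), ab_ob, waist_mean, 9, waist_cut,
                          lower = 55, upper = 160, above = TRUE, strict = TRUE)
  htg <- runif(n_g) < prev[["hypertriglyceridaemia"]]
  tg <- cond_trunclnorm(runif(n_g), htg, log(110), 0.45, 150,
                        lower = 30, upper = 1000)
  hdl_cut <- ifelse(male, 40, 50)
  hdl_mean <- ifelse(male, 49, 59)
  low_hdl <- runif(n_g) < prev[["low_hdl"]]
  hdl <- cond_truncnorm(runif(n_g), !low_hdl, hdl_mean, 11, hdl_cut,
                        lower = 20, upper = 120, above = TRUE, strict = FALSE)
  high_bp <- runif(n_g) < prev[["high_bp"]]
  meds <- high_bp & runif(n_g) < 0.45
  untreated_high <- high_bp & !meds
  sbp <- cond_truncnorm(runif(n_g), untreated_high, 123, 12, 130,
                        lower = 85, upper = 210, above = TRUE, strict = FALSE)
  # treated subjects may sit anywhere plausible under medication
  sbp[meds] <- qtruncnorm(runif(sum(meds)), 134, 13, 100, 210)
  dbp <- qtruncnorm(runif(n_g), 76, 8, 45, pmin(84.9, 130))
  dbp[untreated_high] <- qtruncnorm(runif(sum(untreated_high)), 84, 8, 45, 130)
  dbp[meds] <- qtruncnorm(runif(sum(meds)), 82, 9, 45, 130)

  tibble::tibble(
    age = unname(age), sex = ifelse(male, "male", "female"),
    family_history_dm = famhx, bmi = unname(bmi), waist = unname(waist),
    fpg = unname(fpg), hba1c = unname(hba1c),
    fasting_insulin = unname(homa * 22.5 / mgdl_to_mmol(fpg)),
    homa_ir = unname(homa), triglycerides = unname(tg), hdl = unname(hdl),
    sbp = unname(sbp), dbp = unname(dbp), antihypertensive_use = meds,
    tar_propensity_pct = unname(tar)
  )
}

# truncated-normal draw conditional on being above (or not above) a cut-off
cond_truncnorm <- function(u, flag, mean, sd, cut, lower, upper, above,
                           strict) {
  cut <- rep_len(cut, length(u))
  lo <- ifelse(flag == above, cut, lower)
  hi <- ifelse(flag == above, upper, cut)
  out <- qtruncnorm(u, mean, sd, lo, hi)
  # keep strict/inclusive boundary semantics watertight at float precision
  eps <- 1e-6
  sel <- if (strict) flag == above else flag != above
  out[sel] <- if (strict) pmax(out[sel], cut[sel] + eps)
  else pmin(out[sel], cut[sel] - eps)
  out
}

cond_trunclnorm <- function(u, flag, meanlog, sdlog, cut, lower, upper) {
  p_low <- plnorm(pmax(lower, 1e-9), meanlog, sdlog)
  p_cut <- plnorm(cut, meanlog, sdlog)
  p_hi <- plnorm(upper, meanlog, sdlog)
  p <- ifelse(flag, p_cut + u * (p_hi - p_cut), p_low + u * (p_cut - p_low))
  out <- qlnorm(p, meanlog, sdlog)
  out[!flag] <- pmin(out[!flag], cut - 1e-6)
  out
}

# core trace simulator: returns the glucose vector for one subject
simulate_trace_values <- function(hba1c, tar_propensity_pct, wear_days,
                                  tc, amplitude = NULL) {
  stopifnot(wear_days >= 1)
  n <- as.integer(wear_days) * SAMPLES_PER_DAY
  tod <- (seq_len(n) - 1L) %% SAMPLES_PER_DAY * (5 / 60)
  eag <- 28.7 * hba1c - 46.7
  basal <- tc$basal %||% (tc$basal_intercept + tc$basal_slope * (eag - 100))
  circ <- tc$circadian_amplitude *
    cos(2 * pi * (tod - tc$circadian_peak_hour) / 24)
  day <- rep(seq_len(wear_days), each = SAMPLES_PER_DAY)
  shape <- rep(tc$sustained_fraction, n)
  for (d in seq_len(wear_days)) {
    centres <- tc$meal_times +
      rnorm(length(tc$meal_times), 0, tc$meal_jitter_sd_hours)
    sel <- day == d
    for (k in seq_along(centres)) {
      shape[sel] <- shape[sel] + tc$meal_rel_amplitude[k] *
        exp(-((tod[sel] - centres[k])^2) / (2 * tc$meal_sd_hours^2))
    }
  }
  mu0 <- basal + circ
  if (is.null(amplitude)) {
    target <- tar_propensity_pct / 100
    # reported glucose is rounded to whole mg/dL, so a sample exceeds the
    # 140 threshold iff the latent signal reaches 140.5
    expected_tar <- function(A) {
      mu <- mu0 + A * shape
      if (tc$noise_sd > 0) mean(pnorm((mu - 140.5) / tc$noise_sd))
      else mean(mu > 140)
    }
    amplitude <- if (expected_tar(0) >= target) 0
    else if (expected_tar(3000) <= target) 3000
    else uniroot(function(A) expected_tar(A) - target, c(0, 3000),
                 tol = 1e-4)$root
  }
  noise <- ar1_noise(n, tc$noise_sd, tc$ar1_phi)
  glucose <- clamp(round(mu0 + amplitude * shape + noise),
                   GLUCOSE_RANGE[1], GLUCOSE_RANGE[2])
  list(glucose = glucose, amplitude = amplitude, n = n)
}

trace_timestamps <- function(n, start_date) {
  as.POSIXct(start_date, tz = "UTC") + (seq_len(n) - 1L) * 300
}

#' Simulate a CGM trace for one subject
#'
#' Produces a 5-minute interstitial glucose record (288 samples per complete
#' wear day, clamped to 40-400 mg/dL) for a baseline profile, following the
#' trace model of [trace_config()].
#'
#' @param profile A one-row data frame with at least `subject_id`, `hba1c`
#'   and `tar_propensity_pct` (as produced by [generate_cohort()]).
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @param wear_days Number of complete wear days; defaults to the profile's
#'   `wear_days` column or, failing that, a draw from the configured
#'   wear-day distribution.
#' @param amplitude Optional fixed excursion amplitude overriding the
#'   TAR-propensity calibration (0 gives a deterministic basal+circadian
#'   trace when `noise_sd = 0`).
#' @return A long-format trace tibble (`subject_id`, `timestamp`,
#'   `glucose_mg_dl`).
#' @export
generate_cgm_trace <- function(profile, config, seed = NULL, wear_days = NULL,
                               amplitude = NULL) {
  stopifnot(is.data.frame(profile), nrow(profile) == 1L,
            inherits(config, "cgm_cohort_config"))
  if (is.na(profile$hba1c) || profile$hba1c <= 3 || profile$hba1c >= 20) {
    abort("invalid profile: `hba1c` outside (3, 20)")
  }
  with_seed(seed, {
    wear_days <- wear_days %||% col_or(profile, "wear_days") %||%
      sample(as.integer(names(config$wear_day_distribution)), 1L,
             prob = config$wear_day_distribution)
    sim <- simulate_trace_values(profile$hba1c,
                                 col_or(profile, "tar_propensity_pct", 0),
                                 wear_days, config$trace, amplitude)
    tibble::tibble(
      subject_id = as.character(profile$subject_id),
      timestamp = trace_timestamps(sim$n, config$trace$start_date),
      glucose_mg_dl = sim$glucose
    )
  })
}

#' Simulate CGM traces for a whole cohort
#'
#' Child seeds are derived deterministically per subject from `seed`, so a
#' cohort's traces are reproducible and independent of evaluation order.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A long-format trace tibble covering all subjects.
#' @export
generate_cgm_traces <- function(cohort, config, seed = config$seed) {
  if (is.null(seed)) abort("a seed is mandatory (in the config or as an argument)")
  traces <- purrr::map(seq_len(nrow(cohort)), function(i) {
    generate_cgm_trace(cohort[i, ], config, seed = child_seed(seed, i))
  })
  dplyr::bind_rows(traces)
}

#' Simulate per-subject range metrics without materializing traces
#'
#' Runs the identical trace simulation as [generate_cgm_traces()] (same
#' seeds, same draws) but reduces each trace to its TIR/TAR/TBR summary on
#' the fly, which is considerably lighter for large cohorts.
#'
#' @inheritParams generate_cgm_traces
#' @return A tibble like [compute_time_in_ranges()] output, plus
#'   `wear_days`.
#' @export
simulate_range_metrics <- function(cohort, config, seed = config$seed) {
  if (is.null(seed)) abort("a seed is mandatory (in the config or as an argument)")
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    prof <- cohort[i, ]
    g <- with_seed(child_seed(seed, i), {
      wd <- col_or(prof, "wear_days") %||%
        sample(as.integer(names(config$wear_day_distribution)), 1L,
               prob = config$wear_day_distribution)
      simulate_trace_values(prof$hba1c, col_or(prof, "tar_propensity_pct", 0),
                            wd, config$trace)$glucose
    })
    fr <- range_fractions(g)
    tibble::tibble(subject_id = as.character(prof$subject_id),
                   tir_pct = 100 * fr[["tir"]], tar_pct = 100 * fr[["tar"]],
                   tbr_pct = 100 * fr[["tbr"]], n_samples_used = length(g),
                   wear_days = length(g) %/% SAMPLES_PER_DAY)
  })
}

#' Assign outcomes from a causal logistic model
#'
#' Replaces the cohort's outcome with draws from
#' `Bernoulli(logistic(intercept + sum(coef x covariate) + coef_tar x TAR))`,
#' the generating model used for parameter-recovery studies.  The intercept
#' is auto-tuned so the expected cumulative incidence matches `prevalence`.
#'
#' @param cohort A cohort tibble (needs `age`, `sex`, `family_history_dm`,
#'   `bmi`, `hba1c`).
#' @param metrics Optional per-subject metrics tibble with `subject_id` and
#'   `tar_pct`; when absent the cohort's own `tar_pct` or latent
#'   `tar_propensity_pct` column is used.
#' @param config A [cohort_config()] supplying `causal_coefficients`.
#' @param prevalence Target expected cumulative incidence (default 0.044).
#' @param seed Optional integer seed.
#' @return The cohort with `outcome_t2d_5y` redrawn; the tuned intercept and
#'   the per-subject event probabilities are attached as attributes
#'   `"intercept"` and `"event_probability"`.
#' @export
assign_outcomes_causal <- function(cohort, metrics = NULL, config,
                                   prevalence = 0.044, seed = NULL) {
  stopifnot(inherits(config, "cgm_cohort_config"),
            prevalence > 0, prevalence < 1)
  coefs <- config$causal_coefficients
  needed <- c("age", "sex_male", "family_history", "bmi", "hba1c", "tar_pct")
  if (!all(needed %in% names(coefs))) {
    abort(paste0("causal_coefficients must name: ", paste(needed, collapse = ", ")))
  }
  tar <- if (!is.null(metrics)) {
    m <- dplyr::left_join(cohort["subject_id"],
                          metrics[, c("subject_id", "tar_pct")],
                          by = "subject_id")
    m$tar_pct
  } else {
    col_or(cohort, "tar_pct") %||% col_or(cohort, "tar_propensity_pct")
  }
  sex <- col_or(cohort, "sex")
  covars <- list(age = col_or(cohort, "age"),
                 sex_male = if (!is.null(sex)) sex == "male",
                 family_history = col_or(cohort, "family_history_dm"),
                 bmi = col_or(cohort, "bmi"),
                 hba1c = col_or(cohort, "hba1c"), tar_pct = tar)
  missing_cov <- names(covars)[vapply(covars, function(x) is.null(x) || anyNA(x),
                                      logical(1))]
  if (length(missing_cov)) {
    abort(paste0("missing covariate(s) for causal outcome assignment: ",
                 paste(missing_cov, collapse = ", ")))
  }
  eta <- Reduce(`+`, purrr::imap(covars, function(x, nm) coefs[[nm]] * as.numeric(x)))
  intercept <- uniroot(function(c0) mean(plogis(c0 + eta)) - prevalence,
                       c(-60, 30), tol = 1e-10)$root
  p <- plogis(intercept + eta)
  out <- cohort
  out$outcome_t2d_5y <- with_seed(seed, rbinom(nrow(cohort), 1L, p) == 1L)
  attr(out, "intercept") <- intercept
  attr(out, "event_probability") <- p
  out
}

#' Read / write a cohort table as CSV
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `read_cohort_csv()` returns a tibble; the writer returns the path
#'   invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("subject_id", "age", "sex", "family_history_dm", "bmi", "fpg",
              "hba1c", "outcome_t2d_5y")
  missing_cols <- setdiff(needed, names(out))
  if (length(missing_cols)) {
    abort(paste0("cohort file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out$subject_id <- as.character(out$subject_id)
  out
}

#' Read / write a generator configuration as YAML
#'
#' Serializes the user-specified part of a [cohort_config()] (fitted
#' parameters are recomputed on read).
#'
#' @param config A `cgm_cohort_config`.
#' @param path File path.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "cgm_cohort_config"))
  keep <- c("n_subjects", "n_progressors", "group_moments",
            "group_prevalences", "tar_distribution", "wear_day_distribution",
            "causal_coefficients", "correlation_spec", "seed")
  out <- config[keep]
  out$tar_distribution <- lapply(out$tar_distribution, as.list)
  out$group_prevalences <- lapply(out$group_prevalences, as.list)
  out$wear_day_distribution <- as.list(out$wear_day_distribution)
  out$causal_coefficients <- as.list(out$causal_coefficients)
  out$correlation_spec <- as.list(out$correlation_spec)
  out$trace <- unclass(config$trace)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tc <- do.call(trace_config, raw$trace %||% list())
  gm <- if (is.null(raw$group_moments)) default_group_moments()
  else lapply(raw$group_moments, function(g) lapply(g, unlist))
  cohort_config(
    n_subjects = raw$n_subjects, n_progressors = raw$n_progressors,
    group_moments = gm,
    group_prevalences = lapply(raw$group_prevalences %||%
                                 default_group_prevalences(), unlist),
    tar_distribution = lapply(raw$tar_distribution %||%
                                default_tar_distribution(), unlist),
    wear_day_distribution = unlist(raw$wear_day_distribution %||%
                                     default_wear_day_distribution()),
    causal_coefficients = unlist(raw$causal_coefficients %||%
                                   default_causal_coefficients()),
    correlation_spec = unlist(raw$correlation_spec %||%
                                default_correlation_spec()),
    trace = tc, seed = raw$seed
  )
}
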