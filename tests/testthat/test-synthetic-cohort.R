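test_that("matched-moments cohorts have the configured size and outcome count", {
  cfg <- cohort_config(seed = 101L)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 499)
  expect_equal(sum(co$outcome_t2d_5y), 22)
  # nobody meets confirmed diabetes criteria at baseline
  expect_false(any(ada_diabetes(co$fpg, co$hba1c,
                                second_sample_abnormal = FALSE)))
  expect_true(all(co$fpg > 0))
  expect_true(all(co$hba1c > 3 & co$hba1c < 20))
  expect_true(all(co$bmi > 10 & co$bmi < 80))
  expect_true(all(co$wear_days %in% 2:6))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- small_config(seed = 77L)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)
  tr1 <- generate_cgm_traces(co1[1:4, ], cfg)
  tr2 <- generate_cgm_traces(co2[1:4, ], cfg)
  expect_identical(tr1, tr2)
  # and differs under another seed
  co3 <- generate_cohort(cfg, seed = 78L)
  expect_false(identical(co1$age, co3$age))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_subjects = 10, n_progressors = 10),
               "configuration error")
  gm <- cgmrisk:::default_group_moments()
  gm$progressor$bmi <- c(33.2, -1)
  expect_error(cohort_config(group_moments = gm), "SDs")
  gp <- cgmrisk:::default_group_prevalences()
  gp$progressor[["male"]] <- 1.4
  expect_error(cohort_config(group_prevalences = gp), "prevalences")
  expect_error(cohort_config(wear_day_distribution = c(`2` = 0.5, `3` = 0.6)),
               "sum to 1")
  expect_error(generate_cohort(cohort_config()), "seed")
})

test_that("group-conditional moments converge to the configured targets", {
  cfg <- cohort_config(n_subjects = 10001L, n_progressors = 10000L,
                       seed = 55L)
  co <- generate_cohort(cfg)
  prog <- co[co$outcome_t2d_5y, ]
  n <- nrow(prog)
  for (v in c("age", "bmi", "fpg", "hba1c")) {
    fit <- cfg$fitted$progressor[[v]]
    se <- fit$achieved_sd / sqrt(n)
    expect_lt(abs(mean(prog[[v]]) - fit$achieved_mean), 3 * se)
    sd_se <- fit$achieved_sd / sqrt(2 * (n - 1))
    expect_lt(abs(sd(prog[[v]]) - fit$achieved_sd), 3 * sd_se)
    # the fitted truncated marginals reproduce the requested targets
    expect_equal(fit$achieved_mean, fit$target_mean, tolerance = 1e-3)
    expect_equal(fit$achieved_sd, fit$target_sd, tolerance = 1e-3)
  }
  # HOMA-IR lognormal moments
  tgt <- cfg$group_moments$progressor$homa_ir
  expect_lt(abs(mean(prog$homa_ir) - tgt[1]), 3 * tgt[2] / sqrt(n))
  # insulin is HOMA-consistent
  expect_equal(homa_ir(prog$fasting_insulin, mgdl_to_mmol(prog$fpg)),
               prog$homa_ir)
  # TAR propensity hits the configured median and quartiles
  q <- quantile(prog$tar_propensity_pct, c(0.25, 0.5, 0.75))
  tarspec <- cfg$tar_distribution$progressor
  expect_equal(unname(q[2]), tarspec[["median"]], tolerance = 0.15)
  expect_equal(unname(q[1]), tarspec[["q1"]], tolerance = 0.15)
  # prevalences
  prev <- cfg$group_prevalences$progressor
  for (nm in c("male", "family_history")) {
    obs <- if (nm == "male") mean(prog$sex == "male")
    else mean(prog$family_history_dm)
    expect_lt(abs(obs - prev[[nm]]), 3 * sqrt(prev[[nm]] * (1 - prev[[nm]]) / n))
  }
  # component flags recomputed from values agree with target prevalences
  flags <- metabolic_syndrome(prog)
  for (nm in c("abdominal_obesity", "hypertriglyceridaemia", "low_hdl",
               "high_bp")) {
    expect_lt(abs(mean(flags[[nm]]) - prev[[nm]]),
              3 * sqrt(prev[[nm]] * (1 - prev[[nm]]) / n) + 1e-6)
  }
})

test_that("traces have the exact grid size and stay inside the device range", {
  cfg <- small_config()
  prof <- tibble::tibble(subject_id = "T", hba1c = 5.6,
                         tar_propensity_pct = 4, wear_days = 5L)
  tr <- generate_cgm_trace(prof, cfg, seed = 9L)
  expect_equal(nrow(tr), 5 * 288)
  expect_true(all(tr$glucose_mg_dl >= 40 & tr$glucose_mg_dl <= 400))
  expect_true(all(diff(as.numeric(tr$timestamp)) == 300))
  expect_equal(max(wear_summary(tr)$complete_days), 5)

  # degenerate generator: zero amplitude, zero noise, fixed basal
  flat_cfg <- cohort_config(
    trace = trace_config(basal = 100, circadian_amplitude = 0, noise_sd = 0),
    seed = 1L
  )
  flat <- generate_cgm_trace(prof, flat_cfg, seed = 1L, amplitude = 0)
  expect_true(all(flat$glucose_mg_dl == 100))
  expect_error(generate_cgm_trace(dplyr::mutate(prof, hba1c = 25), cfg,
                                  seed = 1L),
               "hba1c")
})

test_that("fast-path metrics equal metrics computed from full traces", {
  cfg <- small_config(seed = 13L, n = 12L, n_prog = 2L)
  co <- generate_cohort(cfg)
  fast <- simulate_range_metrics(co, cfg)
  full <- compute_time_in_ranges(generate_cgm_traces(co, cfg))
  joined <- dplyr::inner_join(fast, full, by = "subject_id",
                              suffix = c("_fast", "_full"))
  expect_equal(joined$tar_pct_fast, joined$tar_pct_full)
  expect_equal(joined$tir_pct_fast, joined$tir_pct_full)
  expect_equal(joined$n_samples_used_fast, joined$n_samples_used_full)
})

test_that("realized TAR correlates with HbA1c and the coupling is tunable", {
  make_cor <- function(rho) {
    cs <- cgmrisk:::default_correlation_spec()
    cs[["hba1c_tar"]] <- rho
    cfg <- cohort_config(n_subjects = 600L, n_progressors = 26L,
                         correlation_spec = cs, seed = 91L)
    co <- generate_cohort(cfg)
    m <- simulate_range_metrics(co, cfg, seed = 92L)
    d <- dplyr::inner_join(co, m, by = "subject_id")
    cor(d$tar_pct, d$hba1c, method = "spearman")
  }
  weak <- make_cor(0.15)
  strong <- make_cor(0.83)
  expect_gt(weak, 0)
  expect_gt(strong, weak)
  expect_gt(strong, 0.5)
})

test_that("causal outcome assignment hits the target prevalence and null effects vanish", {
  cfg <- cohort_config(n_subjects = 4000L, n_progressors = 22L, seed = 61L)
  co <- generate_cohort(cfg)
  metrics <- tibble::tibble(subject_id = co$subject_id,
                            tar_pct = co$tar_propensity_pct)
  out <- assign_outcomes_causal(co, metrics, cfg, prevalence = 0.044,
                                seed = 62L)
  p <- attr(out, "event_probability")
  expect_equal(mean(p), 0.044, tolerance = 1e-6)
  # expected events on a 499-subject cohort at 4.4% is about 22
  expect_equal(0.044 * 499, 22, tolerance = 0.5)

  # a zero TAR coefficient is recovered as OR ~ 1
  cfg0 <- cfg
  cfg0$causal_coefficients[["tar_pct"]] <- 0
  out0 <- assign_outcomes_causal(co, metrics, cfg0, prevalence = 0.15,
                                 seed = 63L)
  d0 <- dplyr::inner_join(out0, metrics, by = "subject_id")
  f0 <- fit_risk_model(d0)
  i <- which(f0$coefficients$term == "tar_pct")
  expect_gt(f0$coefficients$or_ci_hi[i], 1)
  expect_lt(f0$coefficients$or_ci_lo[i], 1)

  bad <- dplyr::select(co, -"hba1c")
  expect_error(assign_outcomes_causal(bad, metrics, cfg), "hba1c")
})

test_that("generator configs survive a YAML round trip", {
  cfg <- small_config(seed = 7L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  cfg2 <- read_generator_config(path)
  expect_equal(cfg2$n_subjects, cfg$n_subjects)
  expect_equal(cfg2$wear_day_distribution, cfg$wear_day_distribution)
  expect_equal(cfg2$copula_R, cfg$copula_R)
  expect_identical(generate_cohort(cfg2), generate_cohort(cfg))
})
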