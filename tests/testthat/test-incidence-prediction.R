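test_that("cumulative incidence is a simple proportion with guarded domain", {
  expect_equal(round(cumulative_incidence(22, 499), 1), 4.4)
  expect_equal(cumulative_incidence(0, 499), 0)
  expect_equal(cumulative_incidence(499, 499), 100)
  expect_error(cumulative_incidence(5, 0), "positive")
  expect_error(cumulative_incidence(10, 5), "events")
})

test_that("exact Poisson intervals follow the Garwood construction", {
  # 22 events at a rate of 8.3/1,000 PY implies ~2,650.6 person-years
  res <- poisson_rate_ci(22, 22 / 8.3 * 1000, n_at_risk = 499)
  expect_equal(round(res$rate_per_1000py, 1), 8.3)
  expect_equal(round(res$ci_lo, 1), 5.2)
  expect_equal(round(res$ci_hi, 1), 12.6)
  expect_equal(round(res$cumulative_incidence_pct, 1), 4.4)

  # chi-square quantile oracle at k = 10, T = 1,000 PY
  res10 <- poisson_rate_ci(10, 1000)
  expect_equal(res10$ci_lo, 4.7954, tolerance = 1e-4)

  zero <- poisson_rate_ci(0, 500)
  expect_equal(zero$ci_lo, 0)
  expect_gt(zero$ci_hi, 0)
  expect_error(poisson_rate_ci(5, 0), "positive")

  # the interval contains the point rate; width shrinks as events grow
  widths <- vapply(c(5, 20, 80, 320), function(k) {
    r <- poisson_rate_ci(k, k / 8.3 * 1000)
    expect_gte(r$rate_per_1000py, r$ci_lo)
    expect_lte(r$rate_per_1000py, r$ci_hi)
    r$ci_hi - r$ci_lo
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("person-years bookkeeping splits the horizon for progressors", {
  expect_equal(person_years_fixed_horizon(499, 22), 477 * 5 + 22 * 2.5)
  expect_equal(person_years_fixed_horizon(100, 0, horizon_years = 3), 300)
})

test_that("group comparisons use the declared tests", {
  # metabolic syndrome counts: 54/477 non-progressors vs 13/22 progressors
  df <- tibble::tibble(
    outcome = rep(c(FALSE, TRUE), c(477, 22)),
    mets = c(rep(c(TRUE, FALSE), c(54, 423)), rep(c(TRUE, FALSE), c(13, 9)))
  )
  cmp <- compare_groups(df, "outcome", c(mets = "chisq"))
  expect_equal(cmp$test, "chi-square")
  expect_lt(cmp$p_value, 0.001)
  expect_match(cmp$summary_case, "^13 ")

  # identical samples: Mann-Whitney finds nothing
  same <- tibble::tibble(outcome = rep(c(FALSE, TRUE), each = 30),
                         x = rep(seq_len(30), 2))
  ms <- compare_groups(same, "outcome", c(x = "mannwhitney"))
  expect_gt(ms$p_value, 0.95)

  # swapping group labels leaves the Mann-Whitney p unchanged
  set.seed(44)
  rnd <- tibble::tibble(outcome = rep(c(FALSE, TRUE), c(40, 25)),
                        x = c(rnorm(40, 0), rnorm(25, 0.6)))
  p1 <- compare_groups(rnd, "outcome", c(x = "mannwhitney"))$p_value
  rnd$outcome <- !rnd$outcome
  p2 <- compare_groups(rnd, "outcome", c(x = "mannwhitney"))$p_value
  expect_equal(p1, p2)

  expect_error(compare_groups(rnd, "x", c(outcome = "chisq")), "binary")
})

test_that("Pearson correlation handles exact linearity and rejects constants", {
  df <- tibble::tibble(a = 1:20, b = 3 * (1:20) - 5, c = rep(1, 20))
  expect_equal(pearson_correlation(df, "a", "b")$r, 1.0)
  expect_error(pearson_correlation(df, "a", "c"), "constant")
})

test_that("logistic fitting matches closed forms and flags degeneracies", {
  co <- tibble::tibble(outcome_t2d_5y = rep(c(TRUE, FALSE), c(22, 477)))
  f0 <- fit_risk_model(co, outcome_t2d_5y ~ 1)
  expect_equal(f0$coefficients$estimate[1], log(22 / 477), tolerance = 1e-6)

  set.seed(45)
  n <- 400
  dat <- tibble::tibble(x = rnorm(n), z = rnorm(n))
  dat$outcome_t2d_5y <- runif(n) < plogis(-1 + 0.8 * dat$x)
  fit <- fit_risk_model(dat, outcome_t2d_5y ~ x + z)
  expect_equal(fit$coefficients$odds_ratio,
               exp(fit$coefficients$estimate))
  expect_true(all(fit$coefficients$or_ci_lo < fit$coefficients$odds_ratio))

  expect_error(fit_risk_model(dplyr::mutate(dat, outcome_t2d_5y = TRUE),
                              outcome_t2d_5y ~ x),
               "constant")
  # collinear design names the offending column
  dat$x2 <- 2 * dat$x
  expect_error(fit_risk_model(dat, outcome_t2d_5y ~ x + x2), "x2")
  # perfect separation raises an explicit error
  sep <- tibble::tibble(x = c(rnorm(50, -3), rnorm(50, 3)),
                        outcome_t2d_5y = rep(c(FALSE, TRUE), each = 50))
  expect_error(fit_risk_model(sep, outcome_t2d_5y ~ x), "separation")
})

test_that("tidy and glance expose the broom-style summaries", {
  set.seed(46)
  dat <- tibble::tibble(x = rnorm(300))
  dat$outcome_t2d_5y <- runif(300) < plogis(-2 + dat$x)
  fit <- fit_risk_model(dat, outcome_t2d_5y ~ x)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("term", "estimate", "odds_ratio", "or_ci_lo",
                    "or_ci_hi", "p_value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("auc", "brier", "n", "events") %in% names(gl)))
  expect_equal(gl$events, sum(dat$outcome_t2d_5y))
})

test_that("AUC equals brute-force pair counting and respects invariances", {
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.3, 0.2),
                       c(1, 1, 0, 0, 0))$auc, 5 / 6)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "class")

  set.seed(47)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    sc <- sample(round(rnorm(n, 0, 1), 2))  # duplicated values force ties
    y <- runif(n) < plogis(sc)
    if (!any(y) || all(y)) next
    a <- roc_auc(sc, y)$auc
    expect_equal(a, pair_count_auc(sc, y), tolerance = 1e-12)
    # invariant under strictly monotone transforms of the scores
    expect_equal(roc_auc(exp(sc), y)$auc, a, tolerance = 1e-12)
  }
})

test_that("the Brier score is a mean squared probability error", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 8), rep(c(0, 1), 4)), 0.25)
  p <- 22 / 499
  expect_equal(brier_score(rep(p, 499), rep(c(TRUE, FALSE), c(22, 477))),
               p * (1 - p), tolerance = 1e-12)
  expect_error(brier_score(c(0.2, 1.4), c(0, 1)), "\\[0, 1\\]")

  # a fitted model is never worse calibrated in-sample than the base rate
  set.seed(48)
  dat <- tibble::tibble(x = rnorm(400))
  dat$outcome_t2d_5y <- runif(400) < plogis(-2 + 1.2 * dat$x)
  fit <- fit_risk_model(dat, outcome_t2d_5y ~ x)
  base <- brier_score(rep(mean(dat$outcome_t2d_5y), 400),
                      dat$outcome_t2d_5y)
  expect_lte(fit$brier, base)
})
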