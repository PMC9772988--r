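# Epidemiological estimation and risk prediction: cumulative incidence,
# exact Poisson incidence-rate intervals, group comparisons, the adjusted
# logistic model and its discrimination/calibration metrics.

#' Cumulative incidence over a fixed horizon
#'
#' `100 x events / n_at_risk`, in percent.
#'
#' @param events Number of incident cases.
#' @param n_at_risk Population at risk at baseline.
#' @return Cumulative incidence in percent (full precision; report tables
#'   round to one decimal).
#' @examples
#' cumulative_incidence(22, 499) # ~4.4
#' @export
cumulative_incidence <- function(events, n_at_risk) {
  if (any(n_at_risk <= 0)) abort("`n_at_risk` must be positive")
  if (any(events < 0 | events > n_at_risk)) {
    abort("`events` must lie in [0, n_at_risk]")
  }
  100 * events / n_at_risk
}

#' Person-years for a fixed-horizon cohort
#'
#' Book-keeping convention for synthetic cohorts without individual
#' follow-up dates: non-progressors contribute the full horizon and
#' progressors a configurable fraction of it (default one half, the usual
#' assumption of events occurring uniformly over follow-up).
#'
#' @param n_at_risk Cohort size.
#' @param events Number of incident cases.
#' @param horizon_years Follow-up horizon (default 5).
#' @param progressor_fraction Fraction of the horizon a progressor
#'   contributes (default 0.5).
#' @return Total person-years.
#' @export
person_years_fixed_horizon <- function(n_at_risk, events, horizon_years = 5,
                                       progressor_fraction = 0.5) {
  stopifnot(n_at_risk >= events, horizon_years > 0,
            progressor_fraction >= 0, progressor_fraction <= 1)
  (n_at_risk - events) * horizon_years +
    events * horizon_years * progressor_fraction
}

#' Incidence rate with an exact (Garwood) Poisson interval
#'
#' Rate per 1,000 person-years with the exact chi-square (Garwood) interval:
#' with `k` events and `T` thousand person-years,
#' `lo = qchisq(alpha/2, 2k) / (2T)` (zero when `k = 0`) and
#' `hi = qchisq(1 - alpha/2, 2k + 2) / (2T)`.
#'
#' @param events Observed event count (`k >= 0`).
#' @param person_years Person-time at risk, in years (> 0).
#' @param level Confidence level (default 0.95).
#' @param n_at_risk Optional cohort size; when given, cumulative incidence
#'   is included in the result.
#' @return A one-row tibble: `events`, `n_at_risk`, `person_years`,
#'   `cumulative_incidence_pct`, `rate_per_1000py`, `ci_lo`, `ci_hi`,
#'   `level`.
#' @examples
#' poisson_rate_ci(22, 22 / 8.3 * 1000) # rate 8.3, CI ~(5.2, 12.6)
#' @export
poisson_rate_ci <- function(events, person_years, level = 0.95,
                            n_at_risk = NA_integer_) {
  if (person_years <= 0) abort("`person_years` must be positive")
  if (events < 0) abort("`events` must be nonnegative")
  alpha <- 1 - level
  T_thousand <- person_years / 1000
  rate <- events / T_thousand
  lo <- if (events == 0) 0 else qchisq(alpha / 2, 2 * events) / (2 * T_thousand)
  hi <- qchisq(1 - alpha / 2, 2 * events + 2) / (2 * T_thousand)
  tibble::tibble(
    events = as.integer(events), n_at_risk = n_at_risk,
    person_years = person_years,
    cumulative_incidence_pct = if (!is.na(n_at_risk))
      cumulative_incidence(events, n_at_risk) else NA_real_,
    rate_per_1000py = rate, ci_lo = lo, ci_hi = hi, level = level
  )
}

#' Univariate group comparisons for a baseline table
#'
#' Compares variables between outcome groups: proportions with the
#' chi-square test (expected counts are checked and a warning is issued when
#' any is below 5), quantitative variables with the Mann-Whitney test
#' (normal approximation with tie correction).  Summaries are formatted
#' `n (%)` for binary variables and `median [q1, q3]` for continuous ones
#' (means and SDs are returned alongside).
#'
#' @param data A data frame.
#' @param group Name of a binary grouping column (e.g. the outcome).
#' @param vars Named character vector: names are columns of `data`, values
#'   are `"chisq"` or `"mannwhitney"`.
#' @return A tibble with one row per variable: group summaries, the test
#'   name, statistic and p-value.
#' @export
compare_groups <- function(data, group, vars) {
  stopifnot(is.data.frame(data), group %in% names(data))
  g <- data[[group]]
  if (!is_binary(g)) abort("`group` must be binary")
  g <- as.logical(g)
  if (!any(g) || !any(!g)) abort("both groups must be nonempty")
  purrr::imap_dfr(vars, function(type, var) {
    x <- data[[var]]
    if (is.null(x)) abort(paste0("variable `", var, "` not found"))
    if (type == "chisq") {
      xb <- as.logical(x)
      tab <- table(factor(xb, c(FALSE, TRUE)), factor(g, c(FALSE, TRUE)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        warn(paste0("chi-square expected count below 5 for `", var, "`"))
      }
      ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
      tibble::tibble(
        variable = var, test = "chi-square",
        summary_control = sprintf("%d (%s%%)", sum(xb & !g),
                                  fmt1(100 * mean(xb[!g]))),
        summary_case = sprintf("%d (%s%%)", sum(xb & g),
                               fmt1(100 * mean(xb[g]))),
        statistic = unname(ht$statistic), p_value = ht$p.value
      )
    } else if (type == "mannwhitney") {
      ht <- wilcox.test(x[g], x[!g], exact = FALSE, correct = TRUE)
      s <- function(v) sprintf("%s [%s, %s] | %s (%s)",
                               fmt1(median(v)), fmt1(quantile(v, 0.25)),
                               fmt1(quantile(v, 0.75)), fmt1(mean(v)),
                               fmt1(sd(v)))
      tibble::tibble(
        variable = var, test = "Mann-Whitney",
        summary_control = s(x[!g]), summary_case = s(x[g]),
        statistic = unname(ht$statistic), p_value = ht$p.value
      )
    } else {
      abort(paste0("unknown comparison type `", type, "`"))
    }
  })
}

#' Pearson correlation between two quantitative variables
#'
#' @param data A data frame.
#' @param x,y Column names.
#' @return A one-row tibble with `r`, `ci_lo`, `ci_hi`, `p_value`, `n`.
#' @export
pearson_correlation <- function(data, x, y) {
  vx <- data[[x]]
  vy <- data[[y]]
  if (is.null(vx) || is.null(vy)) abort("both columns must exist")
  if (sd(vx) == 0 || sd(vy) == 0) {
    abort("correlation is undefined for a constant variable")
  }
  ht <- cor.test(vx, vy, method = "pearson")
  tibble::tibble(x = x, y = y, r = unname(ht$estimate),
                 ci_lo = ht$conf.int[1], ci_hi = ht$conf.int[2],
                 p_value = ht$p.value, n = sum(complete.cases(vx, vy)))
}

#' ROC area under the curve with a DeLong interval
#'
#' AUC in the rank (Mann-Whitney) formulation: the probability that a
#' randomly chosen case outscores a randomly chosen control, ties counted
#' one half.  The confidence interval is DeLong's.
#'
#' @param scores Numeric risk scores (higher = riskier; orientation is
#'   fixed, not auto-flipped).
#' @param outcomes Binary outcomes (logical or 0/1); both classes required.
#' @param level Confidence level for the DeLong interval.
#' @return A list with `auc`, `ci_lo`, `ci_hi`, `level`.
#' @export
roc_auc <- function(scores, outcomes, level = 0.95) {
  if (!is_binary(outcomes)) abort("`outcomes` must be binary")
  y <- as.logical(outcomes)
  if (!any(y) || !any(!y)) abort("both outcome classes must be present")
  stopifnot(length(scores) == length(y))
  roc <- pROC::roc(response = y, predictor = as.numeric(scores),
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(roc, conf.level = level, method = "delong"))
  list(auc = as.numeric(pROC::auc(roc)), ci_lo = ci[1], ci_hi = ci[3],
       level = level)
}

#' Brier score of probability predictions
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; lower means better calibrated predictions.
#'
#' @param scores Predicted probabilities in \[0, 1\].
#' @param outcomes Binary outcomes (logical or 0/1).
#' @return The Brier score in \[0, 1\].
#' @export
brier_score <- function(scores, outcomes) {
  if (any(scores < 0 | scores > 1)) {
    abort("Brier score needs probabilities in [0, 1]")
  }
  if (!is_binary(outcomes)) abort("`outcomes` must be binary")
  mean((as.numeric(scores) - as.numeric(as.logical(outcomes)))^2)
}

#' Fit the adjusted logistic risk model
#'
#' Binary logistic regression (maximum likelihood via iteratively
#' reweighted least squares) of the 5-year incident-diabetes outcome on the
#' standard confounder set plus time above range, with odds ratios
#' (`exp(coef)`), Wald 95% intervals, in-sample ROC AUC (DeLong interval)
#' and the Brier score.  Singular designs are rejected with the offending
#' columns named, and (quasi-)complete separation raises an explicit error
#' rather than returning divergent estimates.
#'
#' @param data A data frame holding the outcome and all model covariates
#'   (typically a cohort joined with per-subject range metrics).
#' @param formula Model formula; default
#'   `outcome_t2d_5y ~ age + sex + family_history_dm + bmi + hba1c + tar_pct`.
#' @param level Confidence level for Wald and DeLong intervals.
#' @return An object of class `t2d_risk_fit` with [tidy()] and [glance()]
#'   methods; fields include the underlying `glm`, the coefficient table,
#'   fitted probabilities, `auc` (with interval) and `brier`.
#' @export
fit_risk_model <- function(data,
                           formula = outcome_t2d_5y ~ age + sex +
                             family_history_dm + bmi + hba1c + tar_pct,
                           level = 0.95) {
  stopifnot(is.data.frame(data))
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  if (!is_binary(y)) abort("the outcome must be binary")
  y <- as.logical(y)
  if (!any(y) || !any(!y)) abort("the outcome is constant; nothing to fit")
  X <- model.matrix(formula, data = mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort(paste0("singular design: collinear column(s) ",
                 paste(dropped, collapse = ", ")))
  }
  fit <- suppressWarnings(
    glm(formula, data = data, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100))
  )
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (any(!is.finite(beta)) || any(abs(beta[-1L]) > 20) || any(se > 200)) {
    abort("perfect or quasi-complete separation detected: coefficients diverge")
  }
  z <- qnorm(1 - (1 - level) / 2)
  coef_table <- tibble::tibble(
    term = names(beta), estimate = unname(beta), std_error = unname(se),
    statistic = unname(beta / se),
    p_value = 2 * pnorm(-abs(beta / se)),
    odds_ratio = exp(unname(beta)),
    or_ci_lo = exp(unname(beta - z * se)),
    or_ci_hi = exp(unname(beta + z * se))
  )
  prob <- unname(predict(fit, type = "response"))
  auc <- roc_auc(prob, y, level = level)
  structure(
    list(model = fit, formula = formula, coefficients = coef_table,
         fitted_probabilities = prob, outcomes = y,
         auc = auc$auc, auc_ci = c(auc$ci_lo, auc$ci_hi),
         brier = brier_score(prob, y),
         n = length(y), events = sum(y), level = level,
         converged = fit$converged),
    class = "t2d_risk_fit"
  )
}

#' @export
print.t2d_risk_fit <- function(x, ...) {
  cat("Adjusted logistic model for 5-year incident type 2 diabetes\n")
  cat(sprintf("  n = %d subjects, %d events\n", x$n, x$events))
  or <- x$coefficients[x$coefficients$term != "(Intercept)", ]
  for (i in seq_len(nrow(or))) {
    cat(sprintf("  %-22s OR %5.2f (%4.2f, %4.2f)  p = %.3g\n",
                or$term[i], or$odds_ratio[i], or$or_ci_lo[i], or$or_ci_hi[i],
                or$p_value[i]))
  }
  cat(sprintf("  AUC = %.2f (%.2f, %.2f); Brier score = %.3f\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$brier))
  invisible(x)
}

#' Tidy the coefficient table of a risk model fit
#'
#' @param x A `t2d_risk_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term: estimate, standard error,
#'   Wald statistic and p-value, odds ratio and its confidence limits.
#' @export
tidy.t2d_risk_fit <- function(x, ...) x$coefficients

#' One-row model summary of a risk model fit
#'
#' @param x A `t2d_risk_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `events`, `auc`, `auc_ci_lo`, `auc_ci_hi`,
#'   `brier`, deviances and AIC.
#' @export
glance.t2d_risk_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, events = x$events, auc = x$auc,
    auc_ci_lo = x$auc_ci[1], auc_ci_hi = x$auc_ci[2], brier = x$brier,
    null_deviance = x$model$null.deviance, deviance = x$model$deviance,
    aic = x$model$aic, converged = x$converged
  )
}

#' ROC curve of a fitted risk model
#'
#' @param object A `t2d_risk_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.t2d_risk_fit <- function(object, ...) {
  roc <- pROC::roc(response = object$outcomes,
                   predictor = object$fitted_probabilities,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  df <- tibble::tibble(fpr = 1 - roc$specificities, tpr = roc$sensitivities)
  df <- df[order(df$fpr, df$tpr), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.2f)", object$auc)) +
    ggplot2::theme_minimal()
}
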