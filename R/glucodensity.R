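# Glucodensities: per-subject probability densities of interstitial glucose
# on the device support [40, 400] mg/dL, analysed in the 2-Wasserstein
# geometry via their quantile functions.

#' Construct a glucodensity object
#'
#' Usually produced by [estimate_glucodensity()]; exposed for programmatic
#' construction.  The density is renormalized to integrate to one
#' (trapezoidal rule) and must be nonnegative on an equally spaced grid.
#'
#' @param grid Glucose grid (mg/dL), equally spaced, within \[40, 400\].
#' @param density Nonnegative density values on `grid`.
#' @param subject_id Optional subject identifier.
#' @param bandwidth Optional kernel bandwidth used during estimation.
#' @return An object of class `glucodensity` with fields `grid`, `density`,
#'   `subject_id` and `bandwidth`.
#' @export
new_glucodensity <- function(grid, density, subject_id = NA_character_,
                             bandwidth = NA_real_) {
  stopifnot(length(grid) == length(density), length(grid) >= 2L)
  if (any(density < 0)) abort("glucodensity values must be nonnegative")
  total <- trapz(grid, density)
  if (total <= 0) abort("glucodensity must have positive mass")
  structure(
    list(grid = as.numeric(grid), density = as.numeric(density) / total,
         subject_id = subject_id, bandwidth = bandwidth),
    class = "glucodensity"
  )
}

#' @export
print.glucodensity <- function(x, ...) {
  cat("<glucodensity>", if (!is.na(x$subject_id)) paste0(" subject ", x$subject_id), "\n",
      sep = "")
  cat(sprintf("  grid: [%g, %g] mg/dL, %d points; mean %.1f mg/dL\n",
              min(x$grid), max(x$grid), length(x$grid), glucodensity_mean(x)))
  invisible(x)
}

glucodensity_mean <- function(d) trapz(d$grid, d$grid * d$density)

#' Kernel estimate of a subject's glucodensity
#'
#' Estimates the marginal distribution of a subject's glucose samples as a
#' Gaussian kernel density on the fixed device support \[40, 400\] mg/dL,
#' with boundary reflection at both support limits and renormalization to
#' unit mass.  For CGM data on a uniform time grid this density estimates
#' the proportion of monitoring time spent at each glucose concentration.
#'
#' @param x A numeric vector of glucose values (mg/dL), or a single-subject
#'   long-format CGM trace data frame.
#' @param bandwidth Kernel bandwidth in mg/dL; default Silverman's
#'   rule-of-thumb ([stats::bw.nrd0()]) on the input sample.  A degenerate
#'   (single-valued) sample falls back to the minimum bandwidth with a
#'   warning.
#' @param grid_step Grid resolution in mg/dL (default 1).
#' @param min_bandwidth Lower bound for the bandwidth (default 1 mg/dL).
#' @return A [new_glucodensity()] object.
#' @export
estimate_glucodensity <- function(x, bandwidth = NULL, grid_step = 1,
                                  min_bandwidth = 1) {
  subject_id <- NA_character_
  if (is.data.frame(x)) {
    x <- validate_cgm(x)
    if (dplyr::n_distinct(x$subject_id) > 1L) {
      abort("`x` holds several subjects; use estimate_glucodensities()")
    }
    subject_id <- as.character(x$subject_id[1L])
    x <- x$glucose_mg_dl
  }
  x <- as.numeric(x)
  if (!length(x)) abort("cannot estimate a glucodensity from an empty record")
  x <- clamp(x, GLUCOSE_RANGE[1], GLUCOSE_RANGE[2])
  if (is.null(bandwidth)) {
    bandwidth <- if (length(unique(x)) > 1L) bw.nrd0(x) else 0
  }
  if (bandwidth < min_bandwidth) {
    warn(sprintf("bandwidth %.3g below the minimum %.3g mg/dL; using the minimum",
                 bandwidth, min_bandwidth))
    bandwidth <- min_bandwidth
  }
  grid <- seq(GLUCOSE_RANGE[1], GLUCOSE_RANGE[2], by = grid_step)
  # reflect the sample about both support limits so that boundary mass is
  # preserved, then keep the [40,400] restriction of the pooled estimate
  reflected <- c(x, 2 * GLUCOSE_RANGE[1] - x, 2 * GLUCOSE_RANGE[2] - x)
  kde <- density(reflected, bw = bandwidth, from = GLUCOSE_RANGE[1],
                 to = GLUCOSE_RANGE[2], n = length(grid))
  new_glucodensity(grid, pmax(3 * kde$y, 0), subject_id = subject_id,
                   bandwidth = bandwidth)
}

#' Estimate glucodensities for every subject of a trace
#'
#' @param trace A long-format CGM trace with one or more subjects.
#' @inheritParams estimate_glucodensity
#' @return A tibble with columns `subject_id` and `glucodensity`
#'   (a list-column of [new_glucodensity()] objects).
#' @export
estimate_glucodensities <- function(trace, bandwidth = NULL, grid_step = 1) {
  trace <- validate_cgm(trace)
  trace |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      glucodensity = list(estimate_glucodensity(.data$glucose_mg_dl,
                                                bandwidth = bandwidth,
                                                grid_step = grid_step)),
      .groups = "drop"
    ) |>
    dplyr::mutate(glucodensity = purrr::map2(
      .data$glucodensity, .data$subject_id,
      function(d, id) { d$subject_id <- as.character(id); d }
    ))
}

# cumulative distribution function of a glucodensity on its grid
glucodensity_cdf <- function(d) {
  steps <- diff(d$grid) * (head(d$density, -1L) + tail(d$density, -1L)) / 2
  cdf <- c(0, cumsum(steps))
  cdf / cdf[length(cdf)]
}

#' Quantile function of a glucodensity
#'
#' Numerically inverts the CDF on a uniform probability grid (midpoints
#' `(i - 0.5) / n`), yielding the quantile representation used for all
#' Wasserstein computations.
#'
#' @param d A `glucodensity`.
#' @param n_probs Number of probability grid points (default 201).
#' @return An object of class `quantile_curve`: a tibble with columns `prob`
#'   and `quantile` (mg/dL, nondecreasing).
#' @export
quantile_function <- function(d, n_probs = 201L) {
  stopifnot(inherits(d, "glucodensity"), n_probs >= 2L)
  probs <- (seq_len(n_probs) - 0.5) / n_probs
  cdf <- glucodensity_cdf(d)
  q <- approx(x = cdf, y = d$grid, xout = probs, rule = 2, ties = "ordered")$y
  structure(
    tibble::tibble(prob = probs, quantile = cummax(q)),
    class = c("quantile_curve", "tbl_df", "tbl", "data.frame")
  )
}

quantile_vector <- function(d, n_probs = 201L) quantile_function(d, n_probs)$quantile

# rebuild a density on `grid` from a nondecreasing quantile vector
density_from_quantiles <- function(q, probs, grid) {
  q <- cummax(q)
  cdf <- approx(x = q, y = probs, xout = grid, rule = 2, ties = "ordered")$y
  cdf[grid <= q[1L]] <- 0
  cdf[grid >= q[length(q)]] <- 1
  cdf <- cummax(cdf)
  dens <- c(diff(cdf) / diff(grid), 0)
  # centre the finite differences so the mode does not drift half a step
  dens <- (dens + c(0, head(dens, -1L))) / 2
  new_glucodensity(grid, pmax(dens, 0))
}

#' 2-Wasserstein distance between two glucodensities
#'
#' For one-dimensional distributions the 2-Wasserstein (optimal transport)
#' distance equals the L2 distance between quantile functions, evaluated
#' here on a shared uniform probability grid.
#'
#' @param d1,d2 `glucodensity` objects on identical glucose grids.
#' @param n_probs Probability grid resolution (default 201).
#' @return Distance in mg/dL (nonnegative; zero only for equal densities).
#' @export
wasserstein2 <- function(d1, d2, n_probs = 201L) {
  stopifnot(inherits(d1, "glucodensity"), inherits(d2, "glucodensity"))
  if (length(d1$grid) != length(d2$grid) || any(d1$grid != d2$grid)) {
    abort("glucodensities must share a common glucose grid")
  }
  sqrt(mean((quantile_vector(d1, n_probs) - quantile_vector(d2, n_probs))^2))
}

#' Wasserstein barycenter (Frechet mean) of glucodensities
#'
#' The barycenter of one-dimensional distributions under the 2-Wasserstein
#' metric has as quantile function the pointwise mean of the input quantile
#' functions.  Every subject receives equal weight regardless of wear time:
#' the subject, not the sample, is the analysis unit.
#'
#' @param densities A list of `glucodensity` objects on a common grid (or a
#'   tibble from [estimate_glucodensities()]).
#' @param n_probs Probability grid resolution (default 201).
#' @return A `glucodensity` on the common grid.
#' @export
wasserstein_barycenter <- function(densities, n_probs = 201L) {
  densities <- as_density_list(densities)
  if (!length(densities)) abort("need at least one glucodensity")
  grid <- densities[[1L]]$grid
  ok <- vapply(densities, function(d) length(d$grid) == length(grid) &&
                 all(d$grid == grid), logical(1))
  if (!all(ok)) abort("glucodensities must share a common glucose grid")
  probs <- (seq_len(n_probs) - 0.5) / n_probs
  Q <- vapply(densities, quantile_vector, numeric(n_probs), n_probs = n_probs)
  density_from_quantiles(rowMeans(Q), probs, grid)
}

as_density_list <- function(x) {
  if (is.data.frame(x) && "glucodensity" %in% names(x)) return(x$glucodensity)
  if (inherits(x, "glucodensity")) return(list(x))
  stopifnot(is.list(x))
  x
}

#' Permutation test for a difference in mean glucodensities
#'
#' Tests whether two groups of subjects differ in their mean glucose
#' distribution.  The statistic is the squared 2-Wasserstein distance
#' between the group barycenters; its null distribution is obtained by
#' randomly relabelling subjects while preserving the group sizes.  The
#' p-value uses the add-one rule
#' `p = (1 + #\{perm >= observed\}) / (1 + n_permutations)`, which can never
#' be exactly zero.
#'
#' @param group_a,group_b Lists of `glucodensity` objects (or tibbles from
#'   [estimate_glucodensities()]) on a common grid.
#' @param n_permutations Number of random relabellings (default 999; fewer
#'   than 100 triggers a warning).
#' @param seed Optional integer seed for reproducibility.
#' @param n_probs Probability grid resolution (default 201).
#' @return An object of class `cgm_permutation_test`: a list with
#'   `observed_statistic` (mg/dL^2), `p_value`, `n_permutations`, `seed` and
#'   the vector of permuted statistics `null_statistics`.
#' @export
permutation_mean_test <- function(group_a, group_b, n_permutations = 999L,
                                  seed = NULL, n_probs = 201L) {
  group_a <- as_density_list(group_a)
  group_b <- as_density_list(group_b)
  if (!length(group_a) || !length(group_b)) abort("both groups must be nonempty")
  if (n_permutations < 100L) {
    warn("fewer than 100 permutations gives a coarse p-value resolution")
  }
  all_d <- c(group_a, group_b)
  grid <- all_d[[1L]]$grid
  ok <- vapply(all_d, function(d) length(d$grid) == length(grid) &&
                 all(d$grid == grid), logical(1))
  if (!all(ok)) abort("glucodensities must share a common glucose grid")
  n_a <- length(group_a)
  n <- length(all_d)
  Q <- t(vapply(all_d, quantile_vector, numeric(n_probs), n_probs = n_probs))
  stat <- function(idx_a) {
    mean((colMeans(Q[idx_a, , drop = FALSE]) -
            colMeans(Q[-idx_a, , drop = FALSE]))^2)
  }
  observed <- stat(seq_len(n_a))
  null_statistics <- with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) stat(sample.int(n, n_a)), numeric(1))
  })
  structure(
    list(observed_statistic = observed,
         p_value = (1 + sum(null_statistics >= observed)) / (1 + n_permutations),
         n_permutations = as.integer(n_permutations),
         seed = seed,
         n_a = n_a, n_b = n - n_a,
         null_statistics = null_statistics),
    class = "cgm_permutation_test"
  )
}

#' @export
print.cgm_permutation_test <- function(x, ...) {
  cat("Permutation test for equality of mean glucodensities\n")
  cat(sprintf("  groups: %d vs %d subjects\n", x$n_a, x$n_b))
  cat(sprintf("  squared 2-Wasserstein barycenter distance: %.3f mg/dL^2\n",
              x$observed_statistic))
  cat(sprintf("  p = %.4g (%d permutations)\n", x$p_value, x$n_permutations))
  invisible(x)
}

#' Write a per-subject density matrix as CSV
#'
#' First column is the glucose grid; one further column per subject.
#'
#' @param densities Tibble from [estimate_glucodensities()] or list of
#'   `glucodensity` objects.
#' @param path Output file path.
#' @export
write_density_matrix <- function(densities, path) {
  ids <- if (is.data.frame(densities)) as.character(densities$subject_id) else NULL
  densities <- as_density_list(densities)
  ids <- ids %||% vapply(densities, function(d) as.character(d$subject_id), character(1))
  out <- tibble::as_tibble(
    c(list(glucose_mg_dl = densities[[1L]]$grid),
      setNames(lapply(densities, function(d) d$density), make.names(ids, unique = TRUE)))
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Plot a glucodensity
#'
#' @param object A `glucodensity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glucodensity <- function(object, ...) {
  df <- tibble::tibble(glucose = object$grid, density = object$density)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$glucose, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Glucose (mg/dL)", y = "Density",
                  title = if (!is.na(object$subject_id))
                    paste("Glucodensity, subject", object$subject_id)) +
    ggplot2::theme_minimal()
}

#' Overlay group mean glucodensities
#'
#' Plots the Wasserstein barycenter of each group, the distributional
#' analogue of a group mean glucose profile.
#'
#' @param groups Named list of groups, each a list of `glucodensity` objects
#'   or a tibble from [estimate_glucodensities()].
#' @param n_probs Probability grid resolution passed to the barycenter.
#' @return A ggplot object.
#' @export
plot_group_densities <- function(groups, n_probs = 201L) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  bary <- lapply(groups, wasserstein_barycenter, n_probs = n_probs)
  df <- purrr::imap_dfr(bary, function(d, nm) {
    tibble::tibble(group = nm, glucose = d$grid, density = d$density)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$glucose, y = .data$density,
                                   colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Glucose (mg/dL)", y = "Density",
                  colour = NULL, title = "Group mean glucodensities") +
    ggplot2::theme_minimal()
}
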