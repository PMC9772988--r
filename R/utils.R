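# internal numerical helpers

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# trapezoidal integral of y over x
trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)

# quantile of a doubly-truncated normal via inverse-CDF; p may be a vector
qtruncnorm <- function(p, mean, sd, lower = -Inf, upper = Inf) {
  pa <- pnorm(lower, mean, sd)
  pb <- pnorm(upper, mean, sd)
  qnorm(pa + p * (pb - pa), mean, sd)
}

# analytic mean/sd of a truncated normal
truncnorm_moments <- function(mean, sd, lower, upper) {
  za <- (lower - mean) / sd
  zb <- (upper - mean) / sd
  Z <- pnorm(zb) - pnorm(za)
  da <- dnorm(za)
  db <- dnorm(zb)
  ta <- if (is.finite(za)) za * da else 0
  tb <- if (is.finite(zb)) zb * db else 0
  m <- mean + sd * (da - db) / Z
  v <- sd^2 * (1 + (ta - tb) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Find underlying (mean, sd) so that the truncated normal on (lower, upper)
# has the requested target moments.  Parametrised by the upper-bound z-score
# so the near-exponential tail regime stays numerically safe.  Returns the
# underlying parameters together with the moments actually achievable (for
# over-constrained targets the closest family member is used).
fit_truncnorm <- function(target_mean, target_sd, lower, upper) {
  stopifnot(target_sd > 0, lower < upper, target_mean > lower, target_mean < upper)
  objective <- function(par) {
    s <- exp(par[2])
    mu <- if (is.finite(upper)) upper - par[1] * s else par[1]
    mo <- truncnorm_moments(mu, s, lower, upper)
    if (any(!is.finite(mo))) return(1e10)
    sum(((mo - c(target_mean, target_sd)) / target_sd)^2)
  }
  start <- c(if (is.finite(upper)) (upper - target_mean) / target_sd else target_mean,
             log(target_sd))
  # the z floor of -7 keeps pnorm() well away from underflow in the
  # near-exponential upper-tail regime; large positive z is harmless
  opt <- optim(start, objective, method = "L-BFGS-B",
               lower = c(-7, log(target_sd / 10)),
               upper = c(if (is.finite(upper)) 60 else Inf, log(target_sd * 12)))
  s <- exp(opt$par[2])
  mu <- if (is.finite(upper)) upper - opt$par[1] * s else opt$par[1]
  mo <- truncnorm_moments(mu, s, lower, upper)
  list(mean = mu, sd = s, lower = lower, upper = upper,
       achieved_mean = unname(mo["mean"]), achieved_sd = unname(mo["sd"]),
       target_mean = target_mean, target_sd = target_sd)
}

# lognormal (meanlog, sdlog) from a target mean and sd
lognormal_from_moments <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# Quantile-spliced lognormal for the TAR marginal: below the median, log-TAR
# follows N(log median, sd_lo); above it, N(log median, sd_hi).  The two
# scales are set so the printed q1, median and q3 are all matched exactly
# (printed TAR quartiles are strongly asymmetric on the log scale, so a
# single lognormal cannot hit all three).  The upper piece is additionally
# truncated at `upper` percent, which leaves the median and q1 untouched.
fit_tar_splice <- function(median, q1, q3, upper = 95) {
  stopifnot(q1 > 0, q1 < median, median < q3, q3 < upper)
  z75 <- qnorm(0.75)
  sd_lo <- (log(median) - log(q1)) / z75
  sd_hi <- (log(q3) - log(median)) / z75
  # share of the upper piece surviving truncation at `upper`
  adj_hi <- (pnorm((log(upper) - log(median)) / sd_hi) - 0.5) / 0.5
  list(logm = log(median), sd_lo = sd_lo, sd_hi = sd_hi, upper = upper,
       adj_hi = adj_hi)
}

qtar_splice <- function(u, fit) {
  y <- ifelse(u < 0.5,
              fit$logm + qnorm(u) * fit$sd_lo,
              fit$logm + qnorm(0.5 + (u - 0.5) * fit$adj_hi) * fit$sd_hi)
  exp(y)
}

# Spearman rank correlation -> Gaussian copula correlation
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

# draw n rows from a Gaussian copula with correlation matrix R (uniform margins)
copula_uniform <- function(n, R) {
  L <- chol(R)
  z <- matrix(rnorm(n * ncol(R)), nrow = n) %*% L
  pnorm(z)
}

# stationary AR(1) noise with marginal standard deviation sd
ar1_noise <- function(n, sd, phi) {
  if (sd <= 0 || n == 0L) return(numeric(n))
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  innov[1L] <- rnorm(1L, 0, sd)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# derive a reproducible 32-bit child seed from a parent seed and an index
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 7919) %% 2147483629)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# column lookup that tolerates absence (tibbles warn on `$` misses)
col_or <- function(df, name, default = NULL) {
  if (name %in% names(df)) df[[name]] else default
}

is_binary <- function(x) {
  if (is.logical(x)) return(TRUE)
  u <- unique(x[!is.na(x)])
  all(u %in% c(0, 1, TRUE, FALSE))
}

fmt1 <- function(x) formatC(x, format = "f", digits = 1)
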