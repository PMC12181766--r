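# Monte Carlo engine: finite samples from the path models, the adjusted
# OLS test, and rejection-rate estimation.
#
# The hot loop in rejection_rate() is vectorised across replicates: each
# chunk draws an n x m matrix per variable and computes all m partial t
# statistics with column sums.  The partial t used there is the standard
# identity t = r_p * sqrt(n-3) / sqrt(1 - r_p^2) with
# r_p = (r_xy - r_xz * r_zy) / sqrt((1 - r_xz^2)(1 - r_zy^2)), which equals
# the OLS t statistic of the exposure coefficient exactly;
# fit_partial_test() goes through stats::lm and the two routes are
# cross-checked in the test suite.

# Draw m replicate columns of (y, x, z) from a path model; matrices n x m.
draw_columns <- function(model, n, m) {
  Z <- matrix(stats::rnorm(n * m), n, m)
  b <- model$beta; g <- model$gamma
  Y <- b * Z + matrix(stats::rnorm(n * m, sd = sqrt(1 - b^2)), n, m)
  X <- g * Z + matrix(stats::rnorm(n * m, sd = sqrt(1 - g^2)), n, m)
  if (inherits(model, "path_model1")) {
    az <- model$alpha
    Xobs <- X
  } else {
    az <- model$alpha_z
    ax <- model$alpha_x
    Xobs <- ax * X + matrix(stats::rnorm(n * m, sd = sqrt(1 - ax^2)), n, m)
  }
  Zobs <- az * Z + matrix(stats::rnorm(n * m, sd = sqrt(1 - az^2)), n, m)
  list(y = Y, x = Xobs, z = Zobs)
}

#' Draw one finite sample from a path model
#'
#' Generates `n` observations of the observed variables by direct evaluation
#' of the path equations: the latent confounder Z is standard normal, every
#' error term is independent normal with the variance from
#' [error_variances()], so each returned column has population variance 1.
#'
#' @param model A [path_model1()] or [path_model2()] object.
#' @param n Number of observations.
#' @param seed Optional integer seed; if supplied the draw is reproducible
#'   bit-for-bit.
#' @return A data frame with columns `y` (outcome), `x` (observed exposure:
#'   X for model 1, X' for model 2) and `z` (observed confounder Z').
#' @export
draw_sample <- function(model, n, seed = NULL) {
  if (!inherits(model, "path_model")) fp_domain_error("`model` must be a path model")
  n <- check_count(n, "n", min = 1L)
  if (!is.null(seed)) set.seed(check_count(seed, "seed", min = -.Machine$integer.max))
  cols <- draw_columns(model, n, 1L)
  data.frame(y = cols$y[, 1], x = cols$x[, 1], z = cols$z[, 1])
}

#' Adjusted OLS test of the exposure on one sample
#'
#' Fits `y ~ x + z` by ordinary least squares (with intercept), tests the
#' exposure coefficient two-sided, and reports the sample squared partial
#' correlation of y and x given z, computed as \eqn{t^2/(t^2 + n - 3)}.
#'
#' @param sample A data frame with columns `y`, `x`, `z`, e.g. from
#'   [draw_sample()].
#' @param level Significance level for the reject flag (default 0.05).
#' @return A list with `partial_r2`, `t`, `p_value`, `reject`, `n`.
#' @export
fit_partial_test <- function(sample, level = 0.05) {
  if (!is.data.frame(sample) || !all(c("y", "x", "z") %in% names(sample)))
    fp_domain_error("`sample` must be a data frame with columns y, x, z")
  check_level(level)
  n <- nrow(sample)
  if (n < 5L) fp_domain_error("need at least 5 observations (df = n - 3 >= 2)")
  if (stats::sd(sample$x) == 0 || stats::sd(sample$z) == 0)
    fp_singularity_error("singular design: a predictor column is constant")
  fit <- stats::lm(y ~ x + z, data = sample)
  if (fit$qr$rank < 3L)
    fp_singularity_error("singular design: predictors are collinear")
  tab <- summary(fit)$coefficients
  t_val <- tab["x", "t value"]
  p_val <- tab["x", "Pr(>|t|)"]
  list(partial_r2 = t_val^2 / (t_val^2 + n - 3),
       t = t_val, p_value = p_val, reject = p_val < level, n = n)
}

# Vectorised partial t statistics for one chunk of replicate columns.
chunk_partial_t <- function(cols, n) {
  ctr <- function(M) M - rep(colMeans(M), each = nrow(M))
  Y <- ctr(cols$y); X <- ctr(cols$x); Z <- ctr(cols$z)
  syy <- colSums(Y * Y); sxx <- colSums(X * X); szz <- colSums(Z * Z)
  r_xy <- colSums(X * Y) / sqrt(sxx * syy)
  r_zy <- colSums(Z * Y) / sqrt(szz * syy)
  r_xz <- colSums(X * Z) / sqrt(sxx * szz)
  r_p <- (r_xy - r_xz * r_zy) / sqrt((1 - r_xz^2) * (1 - r_zy^2))
  list(t = r_p * sqrt(n - 3) / sqrt(1 - r_p^2), partial_r2 = r_p^2)
}

#' Monte Carlo rejection rate of the adjusted test
#'
#' Simulates `reps` independent datasets of size `n` from a path model, runs
#' the adjusted test of the exposure on each, and returns the proportion of
#' rejections with its binomial Monte Carlo standard error.  Under the
#' models of this package the exposure has no direct effect, so the
#' rejection rate estimates the type I error rate of the adjusted test; the
#' analytic counterpart is [false_power()].
#'
#' All replicates are drawn from a single RNG stream seeded once with
#' `seed` and processed in fixed-size chunks, so results are exactly
#' reproducible for a given seed.
#'
#' @param model A [path_model1()] or [path_model2()] object.
#' @param n Sample size per replicate (integer \eqn{\ge 5}).
#' @param reps Number of replicates (default 10000).
#' @param seed Integer seed (required: every stochastic run is reproducible).
#' @param level Nominal significance level (default 0.05).
#' @param statistic `"partial_t"` (default) for the standard two-sided OLS
#'   t test of the exposure coefficient, or `"r2_ratio"` to reject when the
#'   sample analogue of [f_from_r2()] exceeds the central-F critical value
#'   (a slightly conservative variant, included for comparison).
#' @return A list of class \code{"sim_result"} with `rejection_rate`,
#'   `mc_se` (\eqn{\sqrt{r(1-r)/reps}}), `mean_partial_r2`, `reps_used`.
#' @examples
#' m <- path_model2(1, 1, beta = 0.5, gamma = 0.19)
#' rejection_rate(m, n = 200, reps = 2000, seed = 1)
#' @export
rejection_rate <- function(model, n, reps = 10000, seed, level = 0.05,
                           statistic = c("partial_t", "r2_ratio")) {
  if (!inherits(model, "path_model")) fp_domain_error("`model` must be a path model")
  n <- check_count(n, "n", min = 5L)
  reps <- check_count(reps, "reps", min = 1L)
  if (missing(seed)) fp_domain_error("`seed` is required for stochastic runs")
  check_level(level)
  statistic <- match.arg(statistic)
  set.seed(check_count(seed, "seed", min = -.Machine$integer.max))

  chunk <- max(1L, min(reps, floor(4e6 / n)))
  df2 <- n - 3
  crit_t <- stats::qt(1 - level / 2, df2)
  crit_f <- stats::qf(1 - level, 1, df2)
  rejections <- 0L
  sum_pr2 <- 0
  done <- 0L
  while (done < reps) {
    m <- min(chunk, reps - done)
    st <- chunk_partial_t(draw_columns(model, n, m), n)
    if (statistic == "partial_t") {
      rejections <- rejections + sum(abs(st$t) > crit_t)
    } else {
      rejections <- rejections + sum(st$partial_r2 * df2 > crit_f)
    }
    sum_pr2 <- sum_pr2 + sum(st$partial_r2)
    done <- done + m
  }
  r <- rejections / reps
  structure(list(rejection_rate = r,
                 mc_se = sqrt(r * (1 - r) / reps),
                 mean_partial_r2 = sum_pr2 / reps,
                 reps_used = reps,
                 n = n, level = level, statistic = statistic),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Monte Carlo rejection rate: %.4f (MC SE %.4f, %d reps, n = %d)\n",
              x$rejection_rate, x$mc_se, x$reps_used, x$n))
  cat(sprintf("Mean sample partial R^2: %.6g\n", x$mean_partial_r2))
  invisible(x)
}
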