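# From population squared partial correlation to rejection probability.

#' Hierarchical F expression built from the two R-squareds
#'
#' Computes
#' \deqn{F = \left[\frac{R^2_{Y.X,Z'} - R^2_{Y.Z'}}{1 - R^2_{Y.Z'}}\right]
#'           \times (N - 3),}
#' i.e. the squared partial correlation times the residual degrees of
#' freedom.  Note the left factor's denominator is \eqn{1 - R^2} of the
#' *reduced* model -- that makes the factor exactly the squared partial
#' correlation -- whereas the textbook hierarchical F statistic divides by
#' \eqn{1 - R^2} of the full model.  Both conventions are monotone in the
#' squared partial correlation at fixed N, so shape conclusions about bias
#' curves are unaffected; the Monte Carlo engine uses the standard OLS
#' partial t/F by default (see [rejection_rate()]).
#'
#' @param r2_full R-squared of the outcome on exposure plus confounder.
#' @param r2_reduced R-squared of the outcome on the confounder alone; must
#'   not exceed `r2_full`.
#' @param n Sample size, an integer \eqn{\ge 5}.
#' @return The F value, a scalar.
#' @export
f_from_r2 <- function(r2_full, r2_reduced, n) {
  check_scalar(r2_full, "r2_full")
  check_scalar(r2_reduced, "r2_reduced")
  n <- check_count(n, "n", min = 5L)
  if (r2_reduced >= 1 - 1e-12)
    fp_singularity_error("reduced-model R^2 is 1: partial correlation undefined")
  if (r2_full < r2_reduced - 1e-12)
    fp_domain_error("`r2_full` must be at least `r2_reduced`")
  ((r2_full - r2_reduced) / (1 - r2_reduced)) * (n - 3)
}

#' Analytic false power of the adjusted test
#'
#' Rejection probability of the nominal-`level` test of the exposure
#' coefficient in the regression of Y on (observed exposure, observed
#' confounder), when the population squared partial correlation is
#' `partial_r2`.  Since the models here contain no direct exposure-outcome
#' path, any rejection is a type I error, and this probability is the "false
#' power" (type I error inflation) of the adjusted test.
#'
#' The 1-degree-of-freedom partial F test statistic is distributed
#' noncentral \eqn{F(1, n-3, \lambda)} with
#' \eqn{\lambda = (n-3)\,\rho_p^2/(1-\rho_p^2)}; false power is the mass
#' above the central-F critical value.  When `partial_r2` is 0 the nominal
#' level is returned exactly.  False power is strictly increasing both in
#' `partial_r2` (at fixed n) and in n (at fixed positive `partial_r2`):
#' larger studies buy more power to detect the spurious association.
#'
#' @param partial_r2 Population squared partial correlation(s) in
#'   \eqn{[0, 1)}; vectorised.
#' @param n Sample size, an integer \eqn{\ge 5}.
#' @param level Nominal significance level (default 0.05).
#' @return Rejection probability/ies in \eqn{[level, 1)}.
#' @examples
#' false_power(partial_r2_model2_constrained(0.6, 0.5, 0.19), n = 1000)
#' @export
false_power <- function(partial_r2, n, level = 0.05) {
  if (!is.numeric(partial_r2) || any(!is.finite(partial_r2)) ||
      any(partial_r2 < 0) || any(partial_r2 >= 1))
    fp_domain_error("`partial_r2` must lie in [0, 1)")
  n <- check_count(n, "n", min = 5L)
  check_level(level)
  df2 <- n - 3
  fcrit <- stats::qf(1 - level, 1, df2)
  lambda <- df2 * partial_r2 / (1 - partial_r2)
  out <- stats::pf(fcrit, 1, df2, ncp = lambda, lower.tail = FALSE)
  out[partial_r2 == 0] <- level  # central case: exact by construction
  out
}

#' Bias curve: partial R-squared and false power over a reliability grid
#'
#' Tabulates the squared partial correlation, its derivative, and the
#' analytic false power over a uniform grid of the reliability loading for
#' one of the three model families:
#' \describe{
#'   \item{`"model1"`}{one error-prone confounder; grid variable is
#'     \eqn{\alpha}, the confounder loading.}
#'   \item{`"model2_constrained"`}{exposure and confounder loadings tied,
#'     \eqn{\alpha_x = \alpha_z = \alpha}.}
#'   \item{`"omega"`}{linked loadings \eqn{\alpha_x = \omega\alpha_z + a_0};
#'     grid variable is \eqn{\alpha_z}.}
#' }
#' Derivatives are closed-form for the first two families and central
#' differences (step 1e-6) for the omega family.
#'
#' @param family One of `"model1"`, `"model2_constrained"`, `"omega"`.
#' @inheritParams path_model1
#' @param n Sample size for the false-power column.
#' @param level Nominal significance level.
#' @param omega,a0 Link parameters (omega family only).
#' @param grid_size Number of grid points (default 512).
#' @param alpha_max Upper end of the loading grid (default \code{1 - 1e-6}).
#' @return A data frame of class \code{"bias_curve"} with columns
#'   `alpha`, `partial_r2`, `derivative`, `false_power`.
#' @export
bias_curve <- function(family = c("model1", "model2_constrained", "omega"),
                       beta, gamma, n = 200, level = 0.05,
                       omega = NULL, a0 = 0,
                       grid_size = 512, alpha_max = 1 - 1e-6) {
  family <- match.arg(family)
  check_count(grid_size, "grid_size", min = 3L)
  grid <- seq(0, alpha_max, length.out = grid_size)
  if (family == "model1") {
    pr2 <- vapply(grid, partial_r2_model1, numeric(1), beta = beta, gamma = gamma)
    der <- vapply(grid, d_partial_r2_model1, numeric(1), beta = beta, gamma = gamma)
  } else if (family == "model2_constrained") {
    pr2 <- vapply(grid, partial_r2_model2_constrained, numeric(1),
                  beta = beta, gamma = gamma)
    der <- vapply(grid, d_partial_r2_model2_constrained, numeric(1),
                  beta = beta, gamma = gamma)
  } else {
    if (is.null(omega))
      fp_domain_error("the omega family requires `omega`")
    f <- function(a) partial_r2_omega(a, beta, gamma, omega = omega, a0 = a0)
    pr2 <- vapply(grid, f, numeric(1))
    h <- 1e-6
    der <- vapply(grid, function(a) {
      hi <- min(a + h, alpha_max); lo <- max(a - h, 0)
      (f(hi) - f(lo)) / (hi - lo)
    }, numeric(1))
  }
  out <- data.frame(alpha = grid, partial_r2 = pr2, derivative = der,
                    false_power = false_power(pr2, n = n, level = level))
  attr(out, "params") <- list(family = family, beta = beta, gamma = gamma,
                              n = n, level = level, omega = omega, a0 = a0,
                              grid_size = grid_size, alpha_max = alpha_max)
  class(out) <- c("bias_curve", "data.frame")
  out
}
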