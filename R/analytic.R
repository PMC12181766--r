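# Closed-form squared partial correlations, derivatives, critical points.
#
# Notation: the test of interest regresses the outcome Y on the observed
# exposure and the observed confounder.  "full" R^2 is from that two-predictor
# fit, "reduced" R^2 from the confounder-only fit; the squared partial
# correlation is (full - reduced)/(1 - reduced).

corr_components <- function(c) {
  if (!inherits(c, "corr_matrix3"))
    fp_domain_error("expected a corr_matrix3 (ordering: confounder, exposure, outcome)")
  list(r_xz = c[1, 2], r_zy = c[1, 3], r_xy = c[2, 3])
}

#' Full-model R-squared from a correlation matrix
#'
#' Population R-squared of the regression of the outcome on both the observed
#' exposure and the observed confounder,
#' \deqn{R^2_{Y.X,Z'} = \frac{\rho_{XY}^2 + \rho_{Z'Y}^2
#'        - 2\rho_{XY}\rho_{Z'Y}\rho_{XZ'}}{1 - \rho_{XZ'}^2}.}
#'
#' @param c A [corr_matrix3()] in the package's fixed ordering
#'   (observed confounder, observed exposure, outcome).
#' @return The R-squared, a scalar in \eqn{[0, 1)} for any positive-definite
#'   correlation structure.
#' @export
r2_full_from_corr <- function(c) {
  k <- corr_components(c)
  if (1 - k$r_xz^2 < 1e-12)
    fp_singularity_error(
      "exposure and confounder measurements are collinear (|rho| = 1)")
  val <- (k$r_xy^2 + k$r_zy^2 - 2 * k$r_xy * k$r_zy * k$r_xz) / (1 - k$r_xz^2)
  # fp guard only: exact algebra keeps this in [0, 1) for valid matrices
  if (val < 0 && val > -1e-12) val <- 0
  val
}

#' Reduced-model R-squared from a correlation matrix
#'
#' Population R-squared of the regression of the outcome on the observed
#' confounder alone: \eqn{R^2_{Y.Z'} = \rho_{YZ'}^2}.
#'
#' @inheritParams r2_full_from_corr
#' @return \eqn{\rho_{YZ'}^2}.
#' @export
r2_reduced_from_corr <- function(c) {
  corr_components(c)$r_zy^2
}

#' Squared partial correlation from a correlation matrix
#'
#' The squared partial correlation of the outcome and the observed exposure
#' controlling for the observed confounder,
#' \deqn{R^2_{Y,X.Z'} = \frac{R^2_{Y.X,Z'} - R^2_{Y.Z'}}{1 - R^2_{Y.Z'}},}
#' i.e. the proportion of outcome variance remaining after adjustment that
#' the exposure explains.  In the models of this package there is no direct
#' exposure-outcome path, so any positive value is residual confounding.
#'
#' @inheritParams r2_full_from_corr
#' @return A list of class \code{"partial_r2_result"} with elements
#'   \code{value}, \code{r2_full} and \code{r2_reduced}.
#' @examples
#' partial_r2(implied_corr(path_model1(0.5, 0.13, 0.64)))
#' @export
partial_r2 <- function(c) {
  reduced <- r2_reduced_from_corr(c)
  if (1 - reduced < 1e-12)
    fp_singularity_error(
      "confounder measurement explains all outcome variance (1 - R^2 ~ 0)")
  full <- r2_full_from_corr(c)
  val <- (full - reduced) / (1 - reduced)
  if (val < 0 && val > -1e-12) val <- 0
  structure(list(value = val, r2_full = full, r2_reduced = reduced),
            class = "partial_r2_result")
}

#' @export
print.partial_r2_result <- function(x, ...) {
  cat(sprintf("Squared partial correlation: %.6g  (full R2 %.6g, reduced R2 %.6g)\n",
              x$value, x$r2_full, x$r2_reduced))
  invisible(x)
}

#' Squared partial correlation, one error-prone confounder
#'
#' Closed form for [path_model1()]: substituting the implied correlations
#' gives
#' \deqn{R^2_{Y,X.Z'} =
#'   \frac{\beta^2\gamma^2 (1-\alpha^2)^2}
#'        {(1-\gamma^2\alpha^2)(1-\alpha^2\beta^2)}.}
#' It equals \eqn{(\gamma\beta)^2} at \eqn{\alpha = 0} (no adjustment at all)
#' and 0 at \eqn{\alpha = 1} (perfect adjustment), and is strictly decreasing
#' in \eqn{|\alpha|} in between: better confounder measurement always means
#' less residual confounding here.
#'
#' @inheritParams path_model1
#' @return The squared partial correlation, a scalar.
#' @export
partial_r2_model1 <- function(alpha, beta, gamma) {
  check_loading(alpha, "alpha")
  check_loading(beta, "beta")
  check_loading(gamma, "gamma")
  # (1-a^2) etc. factored as (1-a)(1+a) to avoid cancellation near |a| = 1
  u <- (1 - alpha) * (1 + alpha)
  den <- (u + alpha^2 * (1 - gamma) * (1 + gamma)) *
         (u + alpha^2 * (1 - beta) * (1 + beta))
  if (den < 1e-12)
    fp_singularity_error("degenerate denominator: |alpha*beta| or |alpha*gamma| ~ 1")
  beta^2 * gamma^2 * u^2 / den
}

#' Squared partial correlation, error-prone exposure and confounder
#'
#' Closed form for [path_model2()]:
#' \deqn{R^2_{Y,X'.Z'} =
#'   \frac{\beta^2\gamma^2\alpha_x^2 (1-\alpha_z^2)^2}
#'        {(1-\gamma^2\alpha_x^2\alpha_z^2)(1-\alpha_z^2\beta^2)}.}
#' At fixed \eqn{\alpha_x} this is non-increasing in \eqn{\alpha_z} (a better
#' confounder instrument always helps) and increasing in \eqn{|\alpha_x|}
#' (a noisier exposure instrument attenuates the spurious association too).
#'
#' @inheritParams path_model2
#' @return The squared partial correlation, a scalar.
#' @export
partial_r2_model2 <- function(alpha_x, alpha_z, beta, gamma) {
  check_loading(alpha_x, "alpha_x")
  check_loading(alpha_z, "alpha_z")
  check_loading(beta, "beta")
  check_loading(gamma, "gamma")
  u <- (1 - alpha_z) * (1 + alpha_z)
  den <- (u + alpha_z^2 * (1 - gamma * alpha_x) * (1 + gamma * alpha_x)) *
         (u + alpha_z^2 * (1 - beta) * (1 + beta))
  if (den < 1e-12)
    fp_singularity_error("degenerate denominator in the partial correlation")
  beta^2 * gamma^2 * alpha_x^2 * u^2 / den
}

#' Squared partial correlation under equal reliabilities
#'
#' The constrained case \eqn{\alpha_x = \alpha_z = \alpha} that ties exposure
#' and confounder reliability together.  The curve vanishes at both
#' \eqn{\alpha = 0} and \eqn{\alpha = 1} and is positive in between
#' (whenever \eqn{\beta\gamma \ne 0}), so the bias is non-monotone in the
#' shared reliability -- an artifact of the tie, not a property of confounder
#' reliability per se.
#'
#' @inheritParams path_model1
#' @return The squared partial correlation, a scalar.
#' @seealso [critical_point()] for the interior maximum.
#' @export
partial_r2_model2_constrained <- function(alpha, beta, gamma) {
  partial_r2_model2(alpha, alpha, beta, gamma)
}

#' Squared partial correlation under linked reliabilities
#'
#' Parameterizes the exposure loading through the confounder loading,
#' \eqn{\alpha_x = \omega\alpha_z + a_0}.  For \eqn{a_0 = 0} the closed form
#' reduces to
#' \deqn{R^2_{Y,X'.Z'} =
#'   \frac{(\alpha_z\beta\omega\gamma)^2 (1-\alpha_z^2(2-\alpha_z^2))}
#'        {(1-(\omega\alpha_z^2\gamma)^2)(1-(\alpha_z\beta)^2)},}
#' valid provided \eqn{\omega < 1/(\gamma\alpha_z^2)}.  A notable special
#' case: with \eqn{\beta = \gamma = 1} and \eqn{\omega = -1} the expression
#' simplifies to \eqn{\alpha_z^2/(1+\alpha_z^2)}, monotone increasing in
#' \eqn{\alpha_z} with limit 1/2 as \eqn{\alpha_z \to 1^-}.
#'
#' @param alpha_z Confounder loading, in \eqn{[-1, 1]}.
#' @inheritParams path_model1
#' @param omega Slope linking the loadings.
#' @param a0 Intercept of the link (default 0).
#' @return The squared partial correlation, a scalar.
#' @export
partial_r2_omega <- function(alpha_z, beta, gamma, omega, a0 = 0) {
  check_loading(alpha_z, "alpha_z")
  check_loading(beta, "beta")
  check_loading(gamma, "gamma")
  check_scalar(omega, "omega")
  check_scalar(a0, "a0")
  alpha_x <- omega * alpha_z + a0
  if (a0 == 0 && gamma > 0 && alpha_z != 0) {
    bound <- 1 / (gamma * alpha_z^2)
    if (omega >= bound)
      fp_domain_error(sprintf(
        "reduced form requires omega < 1/(gamma*alpha_z^2) = %g; got omega = %g",
        bound, omega))
  }
  if (abs(alpha_x) > 1)
    fp_domain_error(sprintf(
      "linked exposure loading alpha_x = omega*alpha_z + a0 = %g lies outside [-1, 1]",
      alpha_x))
  if (a0 != 0)
    return(partial_r2_model2(alpha_x, alpha_z, beta, gamma))
  # Stable arrangement of the reduced form: the printed factor
  # 1 - a^2(2 - a^2) equals (1 - a^2)^2, and the denominator factors are
  # rewritten as sums of nonnegative terms so nothing cancels near a = 1.
  u <- (1 - alpha_z) * (1 + alpha_z)
  wg <- omega * gamma
  num <- (alpha_z * beta * omega * gamma)^2 * u^2
  den <- (u * (1 + alpha_z^2) + alpha_z^4 * (1 - wg) * (1 + wg)) *
         (u + alpha_z^2 * (1 - beta) * (1 + beta))
  if (den < 1e-12)
    fp_singularity_error("degenerate denominator in the reduced form")
  num / den
}

#' Derivative of the squared partial correlation in the confounder loading
#'
#' First derivative of [partial_r2_model1()] with respect to \eqn{\alpha}
#' (the square root of the confounder reliability):
#' \deqn{\frac{dR^2}{d\alpha} = \frac{2\alpha(\alpha^2-1)\beta^2\gamma^2
#'   \left[2 - (1+\alpha^2)\gamma^2 + \beta^2(-1+\alpha^2(-1+2\gamma^2))\right]}
#'   {(1-\alpha^2\beta^2)^2 (1-\alpha^2\gamma^2)^2}.}
#' The bracketed factor is positive throughout \eqn{\alpha,\beta,\gamma \in
#' (-1,1)}, so the derivative is negative for \eqn{\alpha \in (0,1)}: the
#' one-error-prone-confounder bias curve is strictly decreasing.
#'
#' @inheritParams path_model1
#' @return The derivative, a scalar (an odd function of \eqn{\alpha}).
#' @export
d_partial_r2_model1 <- function(alpha, beta, gamma) {
  check_loading(alpha, "alpha")
  check_loading(beta, "beta")
  check_loading(gamma, "gamma")
  bracket <- 2 - (1 + alpha^2) * gamma^2 +
    beta^2 * (-1 + alpha^2 * (-1 + 2 * gamma^2))
  den <- (1 - alpha^2 * beta^2)^2 * (1 - alpha^2 * gamma^2)^2
  if (den < 1e-24)
    fp_singularity_error("degenerate denominator in the derivative")
  2 * alpha * (alpha^2 - 1) * beta^2 * gamma^2 * bracket / den
}

# Bracketed polynomial factor of the constrained-model derivative; its root
# in (0, 1) is the critical point because the prefactor 2a(a^2-1)b^2g^2 does
# not vanish there.
model2_bracket <- function(alpha, beta, gamma) {
  -1 + 3 * alpha^2 + alpha^6 * (-1 + 2 * beta^2) * gamma^2 -
    alpha^4 * (2 * beta^2 + gamma^2)
}

#' Derivative of the equal-reliability squared partial correlation
#'
#' First derivative of [partial_r2_model2_constrained()] with respect to the
#' shared loading \eqn{\alpha}:
#' \deqn{\frac{dR^2}{d\alpha} = \frac{2\alpha(\alpha^2-1)\beta^2\gamma^2
#'   \left[-1 + 3\alpha^2 + \alpha^6(2\beta^2-1)\gamma^2
#'         - \alpha^4(2\beta^2+\gamma^2)\right]}
#'   {(1-\alpha^2\beta^2)^2 (1-\alpha^4\gamma^2)^2}.}
#' The bracketed polynomial changes sign exactly once on \eqn{(0,1)}, which
#' yields the interior maximum of the constrained bias curve.
#'
#' @inheritParams path_model1
#' @return The derivative, a scalar.
#' @export
d_partial_r2_model2_constrained <- function(alpha, beta, gamma) {
  check_loading(alpha, "alpha")
  check_loading(beta, "beta")
  check_loading(gamma, "gamma")
  den <- (1 - alpha^2 * beta^2)^2 * (1 - alpha^4 * gamma^2)^2
  if (den < 1e-24)
    fp_singularity_error("degenerate denominator in the derivative")
  2 * alpha * (alpha^2 - 1) * beta^2 * gamma^2 *
    model2_bracket(alpha, beta, gamma) / den
}

#' Critical point of the equal-reliability bias curve
#'
#' Locates the shared reliability loading \eqn{\alpha^* \in (0,1)} at which
#' the constrained squared partial correlation peaks, by bisection on the
#' bracketed polynomial factor of its derivative (the smooth prefactor never
#' vanishes on the open interval, so the bracket carries all interior roots).
#' Analysis is restricted to \eqn{\alpha > 0}; the curve is even in
#' \eqn{\alpha}, so \eqn{-\alpha^*} is the mirrored critical point.
#'
#' @param beta,gamma Path coefficients in \eqn{(0, 1)}.
#' @param tol Bisection tolerance on \eqn{\alpha} (default 1e-12).
#' @return A list of class \code{"critical_point_result"} with elements
#'   \code{alpha_star} (the root, or \code{NA} if the bracket does not change
#'   sign) and \code{shape}, one of \code{"unimodal_interior_max"},
#'   \code{"monotone_decreasing"}, \code{"monotone_nondecreasing"}.
#' @examples
#' critical_point(beta = 0.5, gamma = 0.19)$alpha_star  # ~ 0.597
#' @export
critical_point <- function(beta, gamma, tol = 1e-12) {
  check_loading(beta, "beta")
  check_loading(gamma, "gamma")
  if (beta <= 0 || beta >= 1 || gamma <= 0 || gamma >= 1)
    fp_domain_error("`beta` and `gamma` must lie strictly in (0, 1)")
  lo <- 1e-6; hi <- 1 - 1e-6
  f_lo <- model2_bracket(lo, beta, gamma)
  f_hi <- model2_bracket(hi, beta, gamma)
  if (f_lo * f_hi > 0) {
    # no interior root: classify the curve shape instead
    shape <- classify_monotonicity(
      function(a) partial_r2_model2_constrained(a, beta, gamma))$shape
    return(structure(list(alpha_star = NA_real_, shape = shape),
                     class = "critical_point_result"))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- model2_bracket(mid, beta, gamma)
    if (f_lo * f_mid <= 0) {
      hi <- mid
    } else {
      lo <- mid; f_lo <- f_mid
    }
  }
  structure(list(alpha_star = (lo + hi) / 2, shape = "unimodal_interior_max"),
            class = "critical_point_result")
}

#' @export
print.critical_point_result <- function(x, ...) {
  if (is.na(x$alpha_star)) {
    cat(sprintf("No interior critical point; curve is %s\n", x$shape))
  } else {
    cat(sprintf("Interior maximum at alpha* = %.6f (%s)\n",
                x$alpha_star, x$shape))
  }
  invisible(x)
}

#' Classify the shape of a bias curve on the reliability axis
#'
#' Evaluates a curve on a uniform grid over \eqn{[0, \alpha_{max}]} and
#' classifies it from the signs of successive differences (differences with
#' magnitude below `tol` count as zero):
#' \code{"monotone_decreasing"}, \code{"monotone_nondecreasing"}, or
#' \code{"unimodal_interior_max"} (one sign change, increase then decrease).
#' More than one sign change raises an error, since no curve in this model
#' family can do that -- it would surface a formula bug.
#'
#' @param curve_fn Function of one argument (the loading).
#' @param grid_size Number of grid points (default 512).
#' @param alpha_max Upper end of the grid (default \code{1 - 1e-6}).
#' @param tol Threshold below which a difference counts as zero.
#' @return A list with \code{shape} and \code{alpha_max_at} (grid argmax).
#' @export
classify_monotonicity <- function(curve_fn, grid_size = 512,
                                  alpha_max = 1 - 1e-6, tol = 1e-10) {
  check_count(grid_size, "grid_size", min = 3L)
  grid <- seq(0, alpha_max, length.out = grid_size)
  vals <- vapply(grid, curve_fn, numeric(1))
  d <- diff(vals)
  sgn <- ifelse(abs(d) <= tol, 0L, ifelse(d > 0, 1L, -1L))
  nz <- sgn[sgn != 0L]
  changes <- sum(diff(nz) != 0L)
  if (changes > 1L)
    fp_domain_error("curve changes direction more than once: unexpected shape")
  shape <- if (length(nz) == 0L) {
    "monotone_nondecreasing"
  } else if (changes == 0L) {
    if (nz[1] < 0L) "monotone_decreasing" else "monotone_nondecreasing"
  } else if (nz[1] > 0L) {
    "unimodal_interior_max"
  } else {
    fp_domain_error("curve decreases then increases: unexpected shape")
  }
  list(shape = shape, alpha_max_at = grid[which.max(vals)])
}
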