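#' Path model with one error-prone confounder measurement
#'
#' Defines the standardized-normal generative model
#' \deqn{Y = \beta Z + \epsilon_y,\quad X = \gamma Z + \epsilon_x,\quad
#'       Z' = \alpha Z + e,\quad Z \sim N(0,1),}
#' in which the unobserved confounder Z drives both the outcome Y and the
#' exposure X, and only the error-contaminated Z' is observed.  All error
#' terms are mutually independent, independent of Z, and normal with mean
#' zero; their variances are chosen so that Y, X and Z' each have variance 1
#' (so \eqn{Var(\epsilon_y) = 1-\beta^2} etc.).  There is no direct X to Y
#' path: any adjusted X-Y association is spurious, driven purely by residual
#' confounding.  The reliability of Z' in the classical true-score sense is
#' \eqn{\alpha^2}.
#'
#' @param alpha Standardized loading of Z' on Z, in \eqn{[-1, 1]}.
#' @param beta Path coefficient Z to Y, in \eqn{[-1, 1]}.
#' @param gamma Path coefficient Z to X, in \eqn{[-1, 1]}.
#' @return An object of class \code{c("path_model1", "path_model")}.
#' @seealso [path_model2()] for an error-prone exposure as well,
#'   [implied_corr()], [error_variances()], [draw_sample()].
#' @examples
#' m <- path_model1(alpha = 0.5, beta = 0.13, gamma = 0.64)
#' implied_corr(m)
#' @export
path_model1 <- function(alpha, beta, gamma) {
  check_loading(alpha, "alpha")
  check_loading(beta, "beta")
  check_loading(gamma, "gamma")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = c("path_model1", "path_model"))
}

#' Path model with error-prone exposure and confounder measurements
#'
#' Extends [path_model1()] so that the exposure is also observed through an
#' error-prone instrument:
#' \deqn{Y = \beta Z + \epsilon_y,\quad X = \gamma Z + \epsilon_x,\quad
#'       X' = \alpha_x X + e_x,\quad Z' = \alpha_z Z + e_z,\quad
#'       Z \sim N(0,1).}
#' Only Y, X' and Z' are observed.  All variables are standardized to unit
#' variance; the reliabilities of X' and Z' are \eqn{\alpha_x^2} and
#' \eqn{\alpha_z^2}.
#'
#' @param alpha_x Loading of X' on X, in \eqn{[-1, 1]}.
#' @param alpha_z Loading of Z' on Z, in \eqn{[-1, 1]}.
#' @param beta Path coefficient Z to Y, in \eqn{[-1, 1]}.
#' @param gamma Path coefficient Z to X, in \eqn{[-1, 1]}.
#' @return An object of class \code{c("path_model2", "path_model")}.
#' @examples
#' implied_corr(path_model2(0.6, 0.6, beta = 0.5, gamma = 0.19))
#' @export
path_model2 <- function(alpha_x, alpha_z, beta, gamma) {
  check_loading(alpha_x, "alpha_x")
  check_loading(alpha_z, "alpha_z")
  check_loading(beta, "beta")
  check_loading(gamma, "gamma")
  structure(list(alpha_x = alpha_x, alpha_z = alpha_z,
                 beta = beta, gamma = gamma),
            class = c("path_model2", "path_model"))
}

#' @export
print.path_model1 <- function(x, ...) {
  cat("Path model, one error-prone confounder measurement\n")
  cat(sprintf("  alpha (Z' loading) = %g  [reliability %g]\n",
              x$alpha, x$alpha^2))
  cat(sprintf("  beta  (Z -> Y)     = %g\n", x$beta))
  cat(sprintf("  gamma (Z -> X)     = %g\n", x$gamma))
  invisible(x)
}

#' @export
print.path_model2 <- function(x, ...) {
  cat("Path model, error-prone exposure and confounder measurements\n")
  cat(sprintf("  alpha_x (X' loading) = %g  [reliability %g]\n",
              x$alpha_x, x$alpha_x^2))
  cat(sprintf("  alpha_z (Z' loading) = %g  [reliability %g]\n",
              x$alpha_z, x$alpha_z^2))
  cat(sprintf("  beta    (Z -> Y)     = %g\n", x$beta))
  cat(sprintf("  gamma   (Z -> X)     = %g\n", x$gamma))
  invisible(x)
}

#' Labeled 3x3 correlation matrix
#'
#' Light container used for the correlation matrices implied by the path
#' models.  The variable ordering is fixed as (observed confounder, observed
#' exposure, outcome) throughout the package to prevent index mistakes.
#'
#' @param values Numeric 3x3 matrix; must be symmetric with unit diagonal and
#'   off-diagonal entries in \eqn{[-1, 1]}.
#' @param labels Character vector of three variable names.
#' @return The matrix, with dimnames set, classed \code{"corr_matrix3"}.
#' @export
corr_matrix3 <- function(values, labels) {
  if (!is.matrix(values) || !identical(dim(values), c(3L, 3L)))
    fp_domain_error("`values` must be a 3x3 numeric matrix")
  if (!is.character(labels) || length(labels) != 3L)
    fp_domain_error("`labels` must be three variable names")
  if (max(abs(values - t(values))) > 1e-12)
    fp_domain_error("correlation matrix must be symmetric")
  if (max(abs(diag(values) - 1)) > 1e-12)
    fp_domain_error("correlation matrix must have unit diagonal")
  if (max(abs(values)) > 1 + 1e-12)
    fp_domain_error("correlations must lie in [-1, 1]")
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("corr_matrix3", "matrix"))
}

#' @export
print.corr_matrix3 <- function(x, digits = 4, ...) {
  cat("Implied correlation matrix (", paste(rownames(x), collapse = ", "),
      ")\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Correlation matrix implied by a path model
#'
#' Applies the tracing rules of path analysis to obtain the population
#' correlations among the observed variables.  For [path_model1()] the
#' matrix is over (Z', X, Y) with off-diagonals
#' \eqn{\rho_{X,Z'} = \gamma\alpha}, \eqn{\rho_{Z',Y} = \alpha\beta},
#' \eqn{\rho_{X,Y} = \gamma\beta}; for [path_model2()] it is over
#' (Z', X', Y) with \eqn{\rho_{X',Z'} = \alpha_x\gamma\alpha_z},
#' \eqn{\rho_{Z',Y} = \beta\alpha_z}, \eqn{\rho_{X',Y} = \beta\gamma\alpha_x}.
#'
#' @param model A [path_model1()] or [path_model2()] object.
#' @return A [corr_matrix3()].
#' @export
implied_corr <- function(model) UseMethod("implied_corr")

#' @export
implied_corr.path_model1 <- function(model) {
  a <- model$alpha; b <- model$beta; g <- model$gamma
  v <- matrix(c(1,     g * a, a * b,
                g * a, 1,     g * b,
                a * b, g * b, 1), 3, 3, byrow = TRUE)
  corr_matrix3(v, c("Z'", "X", "Y"))
}

#' @export
implied_corr.path_model2 <- function(model) {
  ax <- model$alpha_x; az <- model$alpha_z
  b <- model$beta; g <- model$gamma
  v <- matrix(c(1,           ax * g * az, b * az,
                ax * g * az, 1,           b * g * ax,
                b * az,      b * g * ax,  1), 3, 3, byrow = TRUE)
  corr_matrix3(v, c("Z'", "X'", "Y"))
}

#' Error-term variances of a standardized path model
#'
#' Returns the variances the independent normal error terms must have for
#' every manifest variable in the model to be standardized to variance 1.
#'
#' @param model A [path_model1()] or [path_model2()] object.
#' @return A named list of error variances, each in \eqn{[0, 1]}:
#'   \code{eps_y} (\eqn{1-\beta^2}), \code{eps_x} (\eqn{1-\gamma^2}),
#'   \code{e_z} (\eqn{1-\alpha_z^2}) and, for model 2 only,
#'   \code{e_x} (\eqn{1-\alpha_x^2}).
#' @export
error_variances <- function(model) UseMethod("error_variances")

#' @export
error_variances.path_model1 <- function(model) {
  list(eps_y = 1 - model$beta^2,
       eps_x = 1 - model$gamma^2,
       e_z   = 1 - model$alpha^2)
}

#' @export
error_variances.path_model2 <- function(model) {
  list(eps_y = 1 - model$beta^2,
       eps_x = 1 - model$gamma^2,
       e_z   = 1 - model$alpha_z^2,
       e_x   = 1 - model$alpha_x^2)
}

#' Write a labeled correlation matrix to CSV
#'
#' @param x A [corr_matrix3()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corr_csv <- function(x, path) {
  if (!inherits(x, "corr_matrix3"))
    fp_domain_error("`x` must be a corr_matrix3")
  df <- data.frame(variable = rownames(x), unclass(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}
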