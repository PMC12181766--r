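# Cost-constrained study design: trade sample size against instrument
# reliability to control type I error inflation from residual confounding.

#' Cost model for a study design
#'
#' Total cost of a design (sample size n, exposure reliability r_x,
#' confounder reliability r_z, each reliability the squared loading) is
#' \deqn{\kappa_n n + \kappa_x \frac{r_x}{1-r_x} + \kappa_z \frac{r_z}{1-r_z}.}
#' The odds transform \eqn{r/(1-r)} makes reliability improvements convex
#' and perfectly reliable instruments unaffordable, which matches how
#' instrument development behaves in practice; it is the package's default
#' and can be replaced via the `reliability_cost` function argument.
#'
#' @param kappa_x,kappa_z Nonnegative cost scales per unit reliability-odds
#'   of the exposure / confounder instrument.
#' @param kappa_n Nonnegative cost per subject.
#' @param budget Positive total budget.
#' @param reliability_cost Function mapping a reliability in \eqn{[0,1)} to
#'   a nonnegative cost multiplier (default the odds transform).
#' @return A list of class \code{"cost_model"}.
#' @export
cost_model <- function(kappa_x, kappa_z, kappa_n, budget,
                       reliability_cost = function(r) r / (1 - r)) {
  check_scalar(kappa_x, "kappa_x"); check_scalar(kappa_z, "kappa_z")
  check_scalar(kappa_n, "kappa_n"); check_scalar(budget, "budget")
  if (kappa_x < 0 || kappa_z < 0 || kappa_n < 0)
    fp_domain_error("cost scales must be nonnegative")
  if (budget <= 0) fp_domain_error("`budget` must be positive")
  structure(list(kappa_x = kappa_x, kappa_z = kappa_z, kappa_n = kappa_n,
                 budget = budget, reliability_cost = reliability_cost),
            class = "cost_model")
}

design_cost <- function(cost, alpha_x, alpha_z, n) {
  cost$kappa_n * n +
    cost$kappa_x * cost$reliability_cost(alpha_x^2) +
    cost$kappa_z * cost$reliability_cost(alpha_z^2)
}

#' Search for the design minimizing false power under a budget
#'
#' Exhaustive grid search over (exposure loading, confounder loading, sample
#' size) triples whose cost fits the budget, minimizing the analytic false
#' power [false_power()] of the adjusted test under the null path model
#' (`beta`, `gamma`, no direct exposure-outcome effect).  Ties are broken by
#' lower cost, then lower n, then higher confounder loading, then higher
#' exposure loading -- so among equally unbiased designs the search prefers
#' the cheapest, smallest study with the best-measured confounder.
#'
#' Note the objective only penalises type I error inflation; designs with a
#' worthless exposure instrument (\eqn{\alpha_x = 0}) trivially attain the
#' nominal level, which is why the reliability-preferring tie-breaks matter.
#' Power to detect a *true* direct effect is outside this model family.
#'
#' @param beta,gamma Path coefficients of the null model.
#' @param cost A [cost_model()].
#' @param level Nominal significance level (default 0.05).
#' @param alpha_grid_size Number of grid points for each loading
#'   (default 41, over \eqn{[0, \alpha_{max}]}).
#' @param alpha_max Largest loading considered (default 0.995).
#' @param n_grid Integer vector of candidate sample sizes; by default 20
#'   values spanning 5 to the largest affordable n (capped at 1e5).
#' @param frontier_points Number of budget values for the cost/false-power
#'   frontier (default 25).
#' @return A list of class \code{"design_result"}: `best` (alpha_x, alpha_z,
#'   n), `achieved_false_power`, `achieved_cost`, and `frontier`, a data
#'   frame of (cost, false_power) pairs non-increasing in false power.
#' @export
optimize_design <- function(beta, gamma, cost, level = 0.05,
                            alpha_grid_size = 41, alpha_max = 0.995,
                            n_grid = NULL, frontier_points = 25) {
  check_loading(beta, "beta"); check_loading(gamma, "gamma")
  if (!inherits(cost, "cost_model")) fp_domain_error("`cost` must be a cost_model")
  check_level(level)
  check_count(alpha_grid_size, "alpha_grid_size", min = 2L)

  if (is.null(n_grid)) {
    n_max <- if (cost$kappa_n > 0) floor(cost$budget / cost$kappa_n) else 1e5
    n_max <- min(n_max, 1e5)
    if (n_max < 5) fp_domain_error("budget infeasible: cannot afford n = 5")
    n_grid <- unique(round(exp(seq(log(5), log(n_max), length.out = 20))))
  }
  n_grid <- sort(unique(as.integer(n_grid)))
  if (any(n_grid < 5)) fp_domain_error("`n_grid` entries must be >= 5")

  a_grid <- seq(0, alpha_max, length.out = alpha_grid_size)
  g <- expand.grid(alpha_x = a_grid, alpha_z = a_grid, n = n_grid,
                   KEEP.OUT.ATTRS = FALSE)
  g$cost <- design_cost(cost, g$alpha_x, g$alpha_z, g$n)
  g <- g[g$cost <= cost$budget, , drop = FALSE]
  if (nrow(g) == 0L)
    fp_domain_error("budget infeasible: no (alpha_x, alpha_z, n) triple affordable")

  pr2 <- mapply(partial_r2_model2, g$alpha_x, g$alpha_z,
                MoreArgs = list(beta = beta, gamma = gamma))
  fpow <- numeric(nrow(g))
  for (nn in unique(g$n)) {
    idx <- g$n == nn
    fpow[idx] <- false_power(pr2[idx], n = nn, level = level)
  }
  g$false_power <- fpow

  ord <- order(g$false_power, g$cost, g$n, -g$alpha_z, -g$alpha_x)
  best <- g[ord[1L], ]

  budgets <- seq(min(g$cost), cost$budget, length.out = frontier_points)
  frontier <- data.frame(
    cost = budgets,
    false_power = vapply(budgets, function(b) min(g$false_power[g$cost <= b]),
                         numeric(1)))

  structure(list(
    best = list(alpha_x = best$alpha_x, alpha_z = best$alpha_z, n = best$n),
    achieved_false_power = best$false_power,
    achieved_cost = best$cost,
    frontier = frontier,
    level = level, beta = beta, gamma = gamma, cost = cost),
    class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("Optimal design under budget", x$cost$budget, "\n")
  cat(sprintf("  alpha_x = %.3f (reliability %.3f), alpha_z = %.3f (reliability %.3f), n = %d\n",
              x$best$alpha_x, x$best$alpha_x^2,
              x$best$alpha_z, x$best$alpha_z^2, x$best$n))
  cat(sprintf("  false power %.4f at level %.3f, cost %.2f\n",
              x$achieved_false_power, x$level, x$achieved_cost))
  invisible(x)
}

#' Spending breakdown of an optimized design
#'
#' Splits the achieved cost of a [optimize_design()] result into subject
#' spend, exposure-instrument spend and confounder-instrument spend, and
#' flags the counterintuitive allocation in which more is invested in
#' measuring the nuisance confounder than the exposure of interest (e.g. a
#' better sodium-intake instrument than energy-intake instrument when sodium
#' drives the confounding).
#'
#' @param result A \code{"design_result"}.
#' @return A data frame with one row per budget item (`subjects`,
#'   `exposure_instrument`, `confounder_instrument`) and columns `spend` and
#'   `share`, with attribute `confounder_over_exposure` (logical flag).
#' @export
allocation_report <- function(result) {
  if (!inherits(result, "design_result"))
    fp_domain_error("`result` must come from optimize_design()")
  cm <- result$cost
  spend <- c(
    subjects = cm$kappa_n * result$best$n,
    exposure_instrument = cm$kappa_x * cm$reliability_cost(result$best$alpha_x^2),
    confounder_instrument = cm$kappa_z * cm$reliability_cost(result$best$alpha_z^2))
  out <- data.frame(item = names(spend), spend = unname(spend),
                    share = if (sum(spend) > 0) unname(spend) / sum(spend) else 0)
  attr(out, "confounder_over_exposure") <-
    spend[["confounder_instrument"]] > spend[["exposure_instrument"]]
  out
}
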