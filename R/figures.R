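# Canonical bias-curve figures.  Every figure writes its underlying numbers
# to CSV next to the image so the curves are regression-testable without
# pixel comparison; the CSVs are byte-stable for a fixed version and grid.

#' Canonical figure specifications
#'
#' The four reference curves shipped with the package, each a fixed
#' parameter set:
#' \describe{
#'   \item{`model1_attenuation`}{one error-prone confounder,
#'     \eqn{\gamma = 0.64, \beta = 0.13}: squared partial correlation
#'     strictly decreasing in \eqn{\alpha}.}
#'   \item{`model2_constrained_bias`}{equal reliabilities,
#'     \eqn{\gamma = 0.19, \beta = 0.50}: non-monotone curve with an
#'     interior maximum at \eqn{\alpha^*}.}
#'   \item{`omega_partial_r2`}{linked loadings with
#'     \eqn{\beta = \gamma = 1, \omega = -1}: non-decreasing in
#'     \eqn{\alpha_z}, converging to 1/2.}
#'   \item{`omega_partial_r2_derivative`}{first derivative of the previous
#'     curve.}
#' }
#'
#' @return Named list of figure specifications.
#' @export
figure_specs <- function() {
  list(
    model1_attenuation = list(
      family = "model1", beta = 0.13, gamma = 0.64,
      alpha_max = 1 - 1e-6, column = "partial_r2",
      ylab = "squared partial correlation",
      main = "Residual confounding vs confounder reliability loading"),
    model2_constrained_bias = list(
      family = "model2_constrained", beta = 0.50, gamma = 0.19,
      alpha_max = 1 - 1e-6, column = "partial_r2",
      ylab = "squared partial correlation",
      main = "Equal-reliability bias curve with interior maximum"),
    omega_partial_r2 = list(
      family = "omega", beta = 1, gamma = 1, omega = -1, a0 = 0,
      alpha_max = 0.999, column = "partial_r2",
      ylab = "squared partial correlation",
      main = "Linked loadings (omega = -1): monotone, limit 1/2"),
    omega_partial_r2_derivative = list(
      family = "omega", beta = 1, gamma = 1, omega = -1, a0 = 0,
      alpha_max = 0.999, column = "derivative",
      ylab = "d(squared partial correlation)/d(alpha_z)",
      main = "Derivative of the linked-loadings curve"))
}

#' Compute the curve behind a canonical figure
#'
#' @param id One of the names of [figure_specs()].
#' @param n Sample size used for the false-power column (default 200).
#' @param level Nominal significance level (default 0.05).
#' @param grid_size Grid points (default 512).
#' @return A [bias_curve()] data frame.
#' @export
figure_curve <- function(id, n = 200, level = 0.05, grid_size = 512) {
  specs <- figure_specs()
  if (!id %in% names(specs))
    fp_domain_error(sprintf("unknown figure id `%s`; known: %s", id,
                            paste(names(specs), collapse = ", ")))
  s <- specs[[id]]
  bias_curve(family = s$family, beta = s$beta, gamma = s$gamma,
             n = n, level = level,
             omega = s$omega, a0 = if (is.null(s$a0)) 0 else s$a0,
             grid_size = grid_size, alpha_max = s$alpha_max)
}

#' Write a bias curve to CSV with a parameter header
#'
#' The file starts with `#`-prefixed comment lines recording the package
#' version and the full parameter set, followed by a regular CSV table
#' (columns `alpha`, `partial_r2`, `derivative`, `false_power`).  Read back
#' with [read_curve_csv()].
#'
#' @param curve A [bias_curve()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  if (!inherits(curve, "bias_curve"))
    fp_domain_error("`curve` must come from bias_curve()")
  p <- attr(curve, "params")
  hdr <- c(
    sprintf("# falsepower %s", as.character(utils::packageVersion("falsepower"))),
    sprintf("# %s", paste(vapply(names(p), function(k) {
      v <- p[[k]]
      sprintf("%s=%s", k, if (is.null(v)) "NULL" else format(v, digits = 15))
    }, character(1)), collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(curve), con, sep = ",",
                     row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a curve CSV written by [write_curve_csv()]
#'
#' @param path File path.
#' @return A data frame (comment header lines are skipped).
#' @export
read_curve_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Render a canonical figure to disk
#'
#' Computes the curve for `id`, writes `<id>.csv` (always) and `<id>.png`
#' (unless `format = "none"`) under `out_dir`.
#'
#' @inheritParams figure_curve
#' @param out_dir Output directory (created if missing).
#' @param format `"png"` or `"none"` (CSV only).
#' @return Named character vector of the files written, invisibly.
#' @export
render_figure <- function(id, out_dir = ".", n = 200, level = 0.05,
                          grid_size = 512, format = c("png", "none")) {
  format <- match.arg(format)
  curve <- figure_curve(id, n = n, level = level, grid_size = grid_size)
  s <- figure_specs()[[id]]
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  csv_path <- file.path(out_dir, paste0(id, ".csv"))
  write_curve_csv(curve, csv_path)
  paths <- c(csv = csv_path)
  if (format == "png") {
    png_path <- file.path(out_dir, paste0(id, ".png"))
    grDevices::png(png_path, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(curve$alpha, curve[[s$column]], type = "l", lwd = 2,
                   xlab = "reliability loading", ylab = s$ylab, main = s$main)
    if (s$column == "derivative") graphics::abline(h = 0, lty = 3)
    paths <- c(paths, png = png_path)
  }
  invisible(paths)
}
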