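# Structured conditions so callers (and the CLI) can distinguish invalid
# parameter domains from algebraic singularities.

fp_domain_error <- function(msg) {
  stop(structure(
    class = c("falsepower_domain_error", "falsepower_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

fp_singularity_error <- function(msg) {
  stop(structure(
    class = c("falsepower_singularity_error", "falsepower_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    fp_domain_error(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}

# Standardized loadings live in [-1, 1]; the closed interval is admitted
# because boundary loadings (zero error variance) are generatively and
# algebraically well defined -- singular denominators are caught separately.
check_loading <- function(x, name) {
  check_scalar(x, name)
  if (abs(x) > 1)
    fp_domain_error(sprintf("`%s` must lie in [-1, 1]; got %g", name, x))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar(x, name)
  if (x != as.integer(x) || x < min)
    fp_domain_error(sprintf("`%s` must be an integer >= %d", name, min))
  invisible(as.integer(x))
}

check_level <- function(level) {
  check_scalar(level, "level")
  if (level <= 0 || level >= 1)
    fp_domain_error("`level` must lie strictly in (0, 1)")
  invisible(level)
}
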