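# Shared helpers: independent numeric oracles used across tests.

# Central-difference derivative; h chosen to balance truncation vs rounding.
num_deriv <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)

# Mixed tolerance: relative with a small absolute floor so comparisons stay
# meaningful where the reference passes through zero.
expect_close <- function(actual, expected, rel = 1e-6, floor = 1e-3) {
  expect_lt(max(abs(actual - expected)), rel * max(abs(expected), floor))
}

# Exact least-squares R^2 from a population correlation matrix (independent
# oracle for the closed-form R^2 expressions): solve the normal equations on
# the implied second moments.
r2_exact_ls <- function(c) {
  Rxx <- unclass(c)[1:2, 1:2]
  rxy <- unclass(c)[1:2, 3]
  drop(t(rxy) %*% solve(Rxx, rxy))
}

# Sample (beta, gamma) pairs comfortably inside the open unit interval.
random_params <- function(n, lo = 0.05, hi = 0.95) {
  data.frame(beta = runif(n, lo, hi), gamma = runif(n, lo, hi))
}

# Independent single-sample partial test, written out from scratch against
# fit_partial_test(): pairwise correlations -> partial correlation -> t.
manual_partial_t <- function(sample) {
  n <- nrow(sample)
  r_xy <- cor(sample$x, sample$y)
  r_zy <- cor(sample$z, sample$y)
  r_xz <- cor(sample$x, sample$z)
  r_p <- (r_xy - r_xz * r_zy) / sqrt((1 - r_xz^2) * (1 - r_zy^2))
  t_val <- r_p * sqrt(n - 3) / sqrt(1 - r_p^2)
  list(t = t_val, p = 2 * pt(-abs(t_val), n - 3), partial_r2 = r_p^2)
}
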