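test_that("full- and reduced-model R^2 from a correlation matrix match hand values and exact least squares", {
  zero <- corr_matrix3(diag(3), c("Z'", "X", "Y"))
  expect_equal(r2_full_from_corr(zero), 0)
  expect_equal(r2_reduced_from_corr(zero), 0)

  single <- corr_matrix3(matrix(c(1, 0, 0, 0, 1, 0.0832, 0, 0.0832, 1), 3, 3),
                         c("Z'", "X", "Y"))
  expect_equal(r2_full_from_corr(single), 0.00692224, tolerance = 1e-12)

  c2 <- implied_corr(path_model2(0.6, 0.6, 0.5, 0.19))
  expect_equal(r2_full_from_corr(c2), 0.0913370, tolerance = 1e-6)
  # independent oracle: R^2 from the normal equations on the implied moments
  expect_equal(r2_full_from_corr(c2), r2_exact_ls(c2), tolerance = 1e-12)
  expect_equal(r2_reduced_from_corr(c2), 0.09, tolerance = 1e-12)

  c1 <- implied_corr(path_model1(0.5, 0.13, 0.64))
  expect_equal(r2_reduced_from_corr(c1), 0.004225, tolerance = 1e-12)
  expect_equal(r2_full_from_corr(c1), r2_exact_ls(c1), tolerance = 1e-12)
})

test_that("squared partial correlation assembles full and reduced R^2", {
  # perfectly measured confounder: adjustment removes all spurious association
  expect_equal(partial_r2(implied_corr(path_model1(1, 0.13, 0.64)))$value, 0)
  # worthless confounder measurement: nothing is removed
  expect_equal(partial_r2(implied_corr(path_model1(0, 0.13, 0.64)))$value,
               (0.64 * 0.13)^2, tolerance = 1e-12)
  res <- partial_r2(implied_corr(path_model2(0.6, 0.6, 0.5, 0.19)))
  expect_equal(res$value, 0.0014693, tolerance = 1e-4)
  expect_equal(res$value, (res$r2_full - res$r2_reduced) / (1 - res$r2_reduced))
  expect_gte(res$r2_full, res$r2_reduced)
})

test_that("singular correlation structures raise singularity errors", {
  collinear <- corr_matrix3(matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3),
                            c("Z'", "X", "Y"))
  expect_error(r2_full_from_corr(collinear),
               class = "falsepower_singularity_error")
  saturated <- corr_matrix3(matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1), 3, 3),
                            c("Z'", "X", "Y"))
  expect_error(partial_r2(saturated), class = "falsepower_singularity_error")
})

test_that("closed-form partial R^2 agrees with the generic matrix route", {
  set.seed(7)
  for (i in 1:100) {
    p <- runif(4, -0.95, 0.95)
    expect_lt(abs(partial_r2_model1(p[1], p[2], p[3]) -
                    partial_r2(implied_corr(path_model1(p[1], p[2], p[3])))$value),
              1e-12)
    expect_lt(abs(partial_r2_model2(p[4], p[1], p[2], p[3]) -
                    partial_r2(implied_corr(path_model2(p[4], p[1], p[2], p[3])))$value),
              1e-12)
  }
  expect_equal(partial_r2_model2_constrained(0.6, 0.5, 0.19),
               partial_r2_model2(0.6, 0.6, 0.5, 0.19))
})

test_that("model-2 partial R^2 vanishes when either instrument is perfect-null", {
  expect_equal(partial_r2_model2(1, 1, 0.4, 0.3), 0)   # no measurement error
  expect_equal(partial_r2_model2(0, 0.6, 0.5, 0.19), 0) # exposure pure noise
  expect_equal(partial_r2_model2_constrained(0, 0.5, 0.19), 0)
  expect_equal(partial_r2_model2_constrained(1, 0.5, 0.19), 0)
})

test_that("both derivative formulas agree with numerical differentiation", {
  set.seed(11)
  for (i in 1:100) {
    a <- runif(1, 0.02, 0.97); b <- runif(1, 0.05, 0.95); g <- runif(1, 0.05, 0.95)
    expect_close(d_partial_r2_model1(a, b, g),
                 num_deriv(function(x) partial_r2_model1(x, b, g), a))
    expect_close(d_partial_r2_model2_constrained(a, b, g),
                 num_deriv(function(x) partial_r2_model2_constrained(x, b, g), a))
  }
  expect_equal(d_partial_r2_model1(0, 0.13, 0.64), 0)
  expect_equal(d_partial_r2_model2_constrained(0, 0.5, 0.19), 0)
  # signs: model-1 curve falls; constrained curve rises then falls
  expect_lt(d_partial_r2_model1(0.5, 0.13, 0.64), 0)
  expect_gt(d_partial_r2_model2_constrained(0.3, 0.5, 0.19), 0)
  expect_lt(d_partial_r2_model2_constrained(0.9, 0.5, 0.19), 0)
})

test_that("partial R^2 is even and its derivative odd in the loading sign", {
  set.seed(13)
  for (i in 1:50) {
    a <- runif(1, 0.05, 0.95); b <- runif(1, 0.05, 0.95); g <- runif(1, 0.05, 0.95)
    ax <- runif(1, 0.05, 0.95)
    expect_equal(partial_r2_model1(-a, b, g), partial_r2_model1(a, b, g))
    expect_equal(partial_r2_model1(a, -b, g), partial_r2_model1(a, b, g))
    expect_equal(partial_r2_model1(a, b, -g), partial_r2_model1(a, b, g))
    expect_equal(partial_r2_model2(-ax, a, b, g), partial_r2_model2(ax, a, b, g))
    expect_equal(d_partial_r2_model1(-a, b, g), -d_partial_r2_model1(a, b, g))
  }
})

test_that("model-1 bias curve is strictly decreasing with known endpoints", {
  set.seed(17)
  grid <- seq(0, 1 - 1e-6, length.out = 256)
  for (i in 1:25) {
    b <- runif(1, 0.05, 0.95); g <- runif(1, 0.05, 0.95)
    vals <- vapply(grid, partial_r2_model1, numeric(1), beta = b, gamma = g)
    expect_true(all(diff(vals) < 0))
    expect_equal(vals[1], (g * b)^2)
    expect_lt(partial_r2_model1(1 - 1e-8, b, g), 1e-6)
  }
})

test_that("constrained curve vanishes at both endpoints and is positive inside", {
  set.seed(19)
  for (i in 1:25) {
    b <- runif(1, 0.05, 0.95); g <- runif(1, 0.05, 0.95)
    expect_equal(partial_r2_model2_constrained(0, b, g), 0)
    expect_lt(partial_r2_model2_constrained(1 - 1e-8, b, g), 1e-6)
    expect_gt(partial_r2_model2_constrained(0.5, b, g), 0)
  }
})

test_that("linked-loadings form matches direct substitution and its known special cases", {
  set.seed(23)
  for (i in 1:50) {
    az <- runif(1, 0.05, 0.95); b <- runif(1, 0.05, 0.95); g <- runif(1, 0.05, 0.95)
    w_hi <- min(1 / az, 1 / (g * az^2)) - 0.01
    w <- runif(1, -1 / az + 0.01, w_hi)
    expect_equal(partial_r2_omega(az, b, g, omega = w),
                 partial_r2_model2(w * az, az, b, g), tolerance = 1e-12)
  }
  # omega = 0: the exposure measurement is pure noise
  expect_equal(partial_r2_omega(0.7, 0.5, 0.19, omega = 0), 0)
  # omega = 1 recovers the equal-reliability case
  expect_equal(partial_r2_omega(0.6, 0.5, 0.19, omega = 1),
               partial_r2_model2_constrained(0.6, 0.5, 0.19), tolerance = 1e-12)
  # beta = gamma = 1, omega = -1 collapses to az^2/(1 + az^2), limit one half
  az <- seq(0, 1 - 1e-6, length.out = 512)
  vals <- vapply(az, partial_r2_omega, numeric(1), beta = 1, gamma = 1, omega = -1)
  expect_equal(vals, az^2 / (1 + az^2), tolerance = 1e-12)
  expect_equal(partial_r2_omega(0.999, 1, 1, -1), 0.49950, tolerance = 1e-4)
  # nonzero intercept case stays monotone nondecreasing
  shape <- classify_monotonicity(
    function(a) partial_r2_omega(a, 1, 1, omega = 0.8, a0 = 0.2),
    alpha_max = 0.999)
  expect_identical(shape$shape, "monotone_nondecreasing")
})

test_that("the linked-loadings constraint is enforced with an explicit bound", {
  err <- tryCatch(partial_r2_omega(0.9, 0.5, 0.8, omega = 2),
                  error = function(e) e)
  expect_s3_class(err, "falsepower_domain_error")
  expect_match(conditionMessage(err), "omega < 1/\\(gamma\\*alpha_z\\^2\\)")
  expect_error(partial_r2_omega(0.9, 0.5, 0.19, omega = 3, a0 = 0.2),
               class = "falsepower_domain_error")  # alpha_x out of range
})

test_that("critical point of the constrained curve matches the dense-grid argmax", {
  cp <- critical_point(beta = 0.5, gamma = 0.19)
  expect_identical(cp$shape, "unimodal_interior_max")
  expect_equal(cp$alpha_star, 0.597, tolerance = 1e-3)
  # derivative vanishes at the root
  expect_lt(abs(d_partial_r2_model2_constrained(cp$alpha_star, 0.5, 0.19)), 1e-8)
  # dense-grid oracle
  grid <- seq(0, 1 - 1e-6, length.out = 1e4)
  vals <- vapply(grid, partial_r2_model2_constrained, numeric(1),
                 beta = 0.5, gamma = 0.19)
  expect_lt(abs(grid[which.max(vals)] - cp$alpha_star), diff(grid[1:2]) * 1.01)
  # holds across random parameter pairs too
  set.seed(29)
  for (i in 1:10) {
    b <- runif(1, 0.1, 0.9); g <- runif(1, 0.1, 0.9)
    cp_i <- critical_point(b, g)
    expect_true(is.finite(cp_i$alpha_star))
    expect_gt(d_partial_r2_model2_constrained(cp_i$alpha_star - 0.01, b, g), 0)
    expect_lt(d_partial_r2_model2_constrained(cp_i$alpha_star + 0.01, b, g), 0)
  }
})

test_that("curve shapes are classified from grid derivative signs", {
  expect_identical(
    classify_monotonicity(function(a) partial_r2_model1(a, 0.13, 0.64))$shape,
    "monotone_decreasing")
  cls <- classify_monotonicity(
    function(a) partial_r2_model2_constrained(a, 0.5, 0.19))
  expect_identical(cls$shape, "unimodal_interior_max")
  expect_equal(cls$alpha_max_at, critical_point(0.5, 0.19)$alpha_star,
               tolerance = 2 / 511)
  expect_identical(
    classify_monotonicity(function(a) partial_r2_omega(a, 1, 1, -1),
                          alpha_max = 0.999)$shape,
    "monotone_nondecreasing")
  expect_error(classify_monotonicity(function(a) sin(6 * a)),
               class = "falsepower_domain_error")
})
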