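test_that("the design matrix z-scores covariates with the population SD", {
  d <- build_design(list(x = c(1, 2, 3)))
  expect_equal(dim(d), c(3, 2))
  expect_equal(d[, "x"], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(d[, "intercept"], rep(1, 3))
  d2 <- build_design(list(a = stats::rnorm(5), b = stats::runif(5)))
  expect_equal(dim(d2), c(5, 3))
  expect_equal(colMeans(d2[, -1]), c(a = 0, b = 0), tolerance = 1e-8)
  expect_equal(
    apply(d2[, -1], 2, function(v) sqrt(mean(v^2))),
    c(a = 1, b = 1),
    tolerance = 1e-8
  )
  expect_error(build_design(list(x = rep(2, 4))), "zero-variance")
  expect_error(build_design(list(x = 1:3, y = 1:4)), "lengths differ")
})

test_that("OLS betas and t statistics match the normal-equations oracle", {
  # exact linear relation: zero residuals, beta recovers the slope
  x <- c(0.5, 1.5, 2, 3.25, 4, 5.5)
  y <- 3 + 2 * x
  d <- build_design(list(x = x))
  f <- fit_glm(d, y)
  sd_pop <- sqrt(mean((x - mean(x))^2))
  expect_equal(unname(f$betas["x"]), 2 * sd_pop, tolerance = 1e-8)
  expect_equal(unname(f$betas["intercept"]), mean(y), tolerance = 1e-8)

  # small noisy problem: hand computation via solve(X'X)
  set.seed(3)
  yn <- y + stats::rnorm(6)
  fn <- fit_glm(d, yn)
  beta_hat <- solve(crossprod(d), crossprod(d, yn))
  res <- yn - d %*% beta_hat
  s2 <- sum(res^2) / (6 - 2)
  se <- sqrt(s2 * diag(solve(crossprod(d))))
  expect_equal(unname(fn$betas), as.numeric(beta_hat), tolerance = 1e-6)
  expect_equal(unname(fn$t_stats), as.numeric(beta_hat) / unname(se), tolerance = 1e-6)

  # joint row permutation leaves the fit unchanged
  p <- sample.int(6)
  fp <- fit_glm(d[p, ], yn[p])
  expect_equal(fp$betas, fn$betas, tolerance = 1e-10)
  expect_error(fit_glm(cbind(d, d[, 2]), yn), "rank-deficient")
})

test_that("random small problems agree with lm to machine precision", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30
    cov1 <- stats::rnorm(n)
    cov2 <- stats::rnorm(n)
    y <- 1 + cov1 - 0.5 * cov2 + stats::rnorm(n)
    d <- build_design(list(a = cov1, b = cov2))
    f <- fit_glm(d, y)
    ref <- stats::lm(y ~ d[, "a"] + d[, "b"])
    expect_lt(max(abs(unname(f$betas) - unname(stats::coef(ref)))), 1e-8)
    expect_lt(
      max(abs(unname(f$t_stats) -
        unname(summary(ref)$coefficients[, "t value"]))),
      1e-6
    )
  }
})

test_that("permutation inference is valid, directional and reproducible", {
  set.seed(11)
  n <- 200
  x1 <- stats::rnorm(n)
  d <- build_design(list(x = x1))
  # strong effect: p pinned at the attainable minimum
  y_strong <- 5 * x1 + stats::rnorm(n, sd = 0.1)
  r <- permutation_test(d, y_strong, n_perm = 500, seed = 2)
  expect_equal(unname(r$p_values["x"]), 1 / 501)
  expect_true(r$significant["x"])
  # reproducibility under a fixed seed
  r2 <- permutation_test(d, y_strong, n_perm = 500, seed = 2)
  expect_identical(r$p_values, r2$p_values)
  expect_length(r$perm_null$x, 500)
  expect_warning(
    permutation_test(d, y_strong, n_perm = 50, seed = 1),
    "coarse"
  )
})

test_that("type-I error matches alpha and null p-values are uniform", {
  # 200 independent null datasets, alpha = 0.01
  set.seed(21)
  n <- 200
  hits <- 0L
  pvals <- numeric(200)
  for (i in 1:200) {
    d <- build_design(list(x = stats::rnorm(n)))
    y <- stats::rnorm(n)
    r <- permutation_test(d, y, n_perm = 199, alpha = 0.01, seed = i)
    pvals[i] <- r$p_values["x"]
    if (r$significant["x"]) hits <- hits + 1L
  }
  # binomial 95% bound for 200 trials at p = 0.01
  expect_lte(hits, stats::qbinom(0.975, 200, 0.01))
  # p-values roughly uniform on their attainable grid (jitter within a grid
  # cell breaks the ties the KS statistic cannot handle)
  grid_jitter <- stats::runif(length(pvals), -0.5, 0.5) / 200
  expect_gt(stats::ks.test(pvals + grid_jitter, "punif")$p.value, 0.001)
})

test_that("the intercept equals the outcome mean under z-scored covariates", {
  set.seed(31)
  d <- build_design(list(
    a = stats::rnorm(50), b = stats::runif(50), c = stats::rexp(50)
  ))
  y <- stats::rnorm(50, mean = 3)
  f <- fit_glm(d, y)
  expect_equal(unname(f$betas["intercept"]), mean(y), tolerance = 1e-8)
})
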