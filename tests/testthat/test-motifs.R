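test_that("PCA recovers a rank-1 shape construction", {
  r1 <- rank1_profiles(60, seed = 42)
  fit <- fit_shape_pca(r1$profiles, n_comp = 1)
  expect_gt(fit$var_explained[1], 0.999)
  expect_gt(abs(sum(fit$components[, 1] * r1$v)), 0.999)
  expect_equal(fit$mean_profile, r1$mu + r1$v * mean(r1$scores),
    tolerance = 1e-8
  )
})

test_that("components are orthonormal, centered and sign-deterministic", {
  set.seed(9)
  x <- matrix(stats::rnorm(48 * 80), 48, 80) + 10
  fit <- fit_shape_pca(x, n_comp = 5)
  expect_equal(crossprod(fit$components), diag(5), tolerance = 1e-8)
  expect_lt(max(abs(rowMeans(fit$scores))), 1e-8)
  expect_true(all(diff(fit$var_explained) <= 1e-12))
  expect_equal(sum(fit$eigenvalues) / sum(fit$eigenvalues), 1)
  # full-rank variance accounting
  full <- fit_shape_pca(x, n_comp = 48)
  expect_equal(sum(full$var_explained), 1, tolerance = 1e-8)
  # permuting input cycles leaves the components identical
  perm <- fit_shape_pca(x[, sample.int(80)], n_comp = 5)
  expect_equal(perm$components, fit$components, tolerance = 1e-8)
  expect_error(fit_shape_pca(x[, 1:4], n_comp = 5))
})

test_that("PCA matches an explicit eigendecomposition and prcomp oracle", {
  set.seed(17)
  x <- matrix(stats::rnorm(48 * 150), 48, 150)
  x <- x + outer(sin(phase_grid(48)), stats::rnorm(150, sd = 3))
  fit <- fit_shape_pca(x, n_comp = 4)
  # brute-force covariance eigendecomposition
  xc <- x - rowMeans(x)
  ev <- eigen(xc %*% t(xc) / (ncol(x) - 1), symmetric = TRUE)
  expect_equal(abs(diag(crossprod(fit$components, ev$vectors[, 1:4]))),
    rep(1, 4),
    tolerance = 1e-8
  )
  expect_equal(
    fit$var_explained,
    (ev$values / sum(ev$values))[1:4],
    tolerance = 1e-10
  )
  # independent library implementation agrees
  pr <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  expect_equal(abs(diag(crossprod(fit$components, pr$rotation[, 1:4]))),
    rep(1, 4),
    tolerance = 1e-8
  )
  expect_equal(abs(stats::cor(fit$scores[1, ], pr$x[, 1])), 1, tolerance = 1e-10)
})

test_that("exemplars project extreme scores back into profile space", {
  r1 <- rank1_profiles(60, seed = 42)
  fit <- fit_shape_pca(r1$profiles, n_comp = 1)
  ex <- motif_exemplars(fit, 1)
  true_min <- r1$mu + r1$v * min(r1$scores)
  true_max <- r1$mu + r1$v * max(r1$scores)
  # component sign is fixed internally; compare as unordered pair
  d1 <- max(abs(ex$min_profile - true_min)) + max(abs(ex$max_profile - true_max))
  d2 <- max(abs(ex$min_profile - true_max)) + max(abs(ex$max_profile - true_min))
  expect_lt(min(d1, d2), 1e-6)
  expect_length(ex$min_waveform, 480)
  expect_error(motif_exemplars(fit, 3), "not fitted")
  # degenerate all-zero scores: both exemplars collapse onto the mean
  fit0 <- fit
  fit0$scores[] <- 0
  ex0 <- motif_exemplars(fit0, 1)
  expect_equal(ex0$min_profile, fit$mean_profile)
  expect_equal(ex0$max_profile, fit$mean_profile)
})

test_that("dynamic-simulation exemplars sit on opposite sides of 0.5 asymmetry", {
  # deterministic miniature of the dynamic world: alternating schematic cycles
  fa <- schematic_cycle("fast_ascent", 128, 0.4)$waveform
  fd <- schematic_cycle("fast_descent", 128, 0.4)$waveform
  sn <- schematic_cycle("sinusoid", 128, 0)$waveform
  x <- rep(c(fa, sn, fd, sn), 10)
  tr <- frequency_transform(x, 128)
  tab <- detect_cycles(tr)
  prof <- align_cycles(tr, tab)
  # the symmetric fast-ascent / fast-descent construction is rank 1
  fit <- fit_shape_pca(prof, n_comp = 1)
  ex <- motif_exemplars(fit, 1)
  a2d_of <- function(w) {
    trw <- frequency_transform(rep(w, 8), length(w))
    tw <- detect_cycles(trw)
    mean(tw$a2d_ratio[tw$good])
  }
  sides <- c(a2d_of(ex$min_waveform), a2d_of(ex$max_waveform))
  expect_lt(min(sides), 0.5)
  expect_gt(max(sides), 0.5)
})

test_that("split-half stability separates structure from noise", {
  r1 <- rank1_profiles(80, seed = 4)
  st <- split_half_stability(r1$profiles, n_comp = 1, n_iter = 100, seed = 1)
  expect_true(all(st$shape_correlations[, 1] > 0.99))
  expect_equal(dim(st$var_explained), c(100, 1, 2))
  # pure-noise profiles are far less reproducible
  noise <- matrix(stats::rnorm(48 * 80), 48, 80)
  stn <- split_half_stability(noise, n_comp = 1, n_iter = 100, seed = 1)
  expect_lt(mean(stn$shape_correlations), mean(st$shape_correlations))
  # determinism under a fixed seed
  st2 <- split_half_stability(r1$profiles, n_comp = 1, n_iter = 100, seed = 1)
  expect_identical(st$shape_correlations, st2$shape_correlations)
})
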