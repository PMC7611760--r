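# Build a trace object directly so degenerate phase paths can be tested
# without constructing a signal that produces them.
fake_trace <- function(wrapped, signal = NULL, fs = 100) {
  n <- length(wrapped)
  if (is.null(signal)) signal <- sin(wrapped)
  structure(
    list(
      phase_wrapped = wrapped,
      phase_unwrapped = cycleshape:::unwrap_phase(wrapped),
      if_hz = rep(1, n), ia = rep(1, n), signal = signal, fs = fs
    ),
    class = "cycleshape_trace"
  )
}

test_that("clean sinusoid cycles are detected and all flagged good", {
  tr <- sinusoid_trace(8, 1000, 8)
  tab <- detect_cycles(tr)
  expect_gte(nrow(tab), 5) # interior cycles only; edges are not emitted
  expect_true(all(tab$good))
  expect_true(all(diff(tab$start) > 0))
  expect_true(all(tab$end - tab$start == tab$duration_samples))
  # strict control-point ordering on every good cycle
  with(
    tab,
    expect_true(all(asc_start < peak & peak < desc &
      desc < trough & trough < asc_end))
  )
})

test_that("phase reversals and late starts disqualify a cycle", {
  step <- 2 * pi / 64
  c1 <- seq(0, 2 * pi - step, by = step)
  w <- rep(c1, 4)
  # interior reversal in cycle 2
  w_rev <- w
  w_rev[64 + 32] <- w_rev[64 + 31] - 0.2
  tab <- detect_cycles(fake_trace(w_rev))
  expect_false(tab$good[1]) # the reversal falls in the first emitted cycle
  expect_true(tab$good[2])
  # a cycle whose first wrapped sample starts beyond pi/24
  c_late <- seq(0.15, 2 * pi - 0.02, length.out = 64)
  w_late <- c(c1, c_late, c1, c1)
  tab2 <- detect_cycles(fake_trace(w_late))
  expect_false(tab2$good[1]) # the late-start cycle
  expect_true(any(tab2$good))
})

test_that("control-point ratios of a pure sinusoid equal one half", {
  tr <- sinusoid_trace(8, 1000, 6)
  cyc <- first_good_cycle(tr)
  cp <- control_points_and_ratios(tr$signal, cyc)
  expect_equal(cp$p2t_ratio, 0.5, tolerance = 0.01)
  expect_equal(cp$a2d_ratio, 0.5, tolerance = 0.01)
  # quarter-period spacing of the control points
  q <- 1000 / 8 / 4
  expect_equal(cp$control$peak - cp$control$asc_start, q, tolerance = 0.05)
  expect_equal(cp$control$trough - cp$control$desc, q, tolerance = 0.05)
})

test_that("parabolic vertex and linear zero-crossing refinement match closed forms", {
  # peak neighbourhood (1, 3, 2): vertex offset (y- - y+)/(2(y- - 2 y0 + y+)) = +1/6
  imf <- c(-0.6, -0.2, 1, 3, 2, -0.2, -2.5, -1, -0.2, 0.4, 0.8, 1.2)
  cp <- control_points_and_ratios(imf, c(1, 10))
  expect_equal(cp$control$peak, 3 + 1 / 6, tolerance = 1e-12)
  # ascending crossing between samples valued (-0.2, 1): offset 0.2/1.2
  expect_equal(cp$control$asc_start, 1 + 0.2 / 1.2, tolerance = 1e-12)
  # final ascending crossing between (-0.2, 0.4): offset 0.2/0.6
  expect_equal(cp$control$asc_end, 8 + 0.2 / 0.6, tolerance = 1e-12)
  # crossing between (-0.2, 0.6) sits a quarter sample along
  expect_equal(0.2 / (0.2 + 0.6), 0.25)
  expect_error(
    control_points_and_ratios(c(-1, 1, -1, 1, -1, 1, -1, 1), c(1, 6)),
    "control points"
  )
})

test_that("schematic edge asymmetries land on the expected side of 0.5", {
  tr_a <- schematic_trace("fast_ascent", 256, 0.3, n_cycles = 30)
  tr_d <- schematic_trace("fast_descent", 256, 0.3, n_cycles = 30)
  a <- detect_cycles(tr_a)
  d <- detect_cycles(tr_d)
  expect_gt(mean(a$a2d_ratio[a$good] < 0.5), 0.95)
  expect_gt(mean(d$a2d_ratio[d$good] > 0.5), 0.95)
})

test_that("cycle selection applies bounds, percentiles and covariates", {
  tr <- sinusoid_trace(8, 1000, 14)
  tab <- detect_cycles(tr)
  tab <- tab[tab$good, , drop = FALSE]
  n <- nrow(tab)
  expect_gte(n, 10)
  # absolute amplitude floor between 3rd and 4th smallest keeps n - 3
  tab$max_ia <- seq_len(n) / n
  floor_val <- (tab$max_ia[3] + tab$max_ia[4]) / 2
  expect_equal(nrow(select_cycles(tab, list(amp_floor = floor_val))), n - 3)
  # percentile floor removes everything below the 10% quantile
  tab2 <- tab
  tab2$max_ia <- seq_len(n)
  kept <- select_cycles(tab2, list(amp_percentile = 0.1))
  expect_equal(
    nrow(kept),
    sum(tab2$max_ia >= stats::quantile(tab2$max_ia, 0.1))
  )
  expect_lt(nrow(kept), n)
  # IF ceiling removes the flagged cycle
  tab3 <- tab
  tab3$if_max[4] <- 19
  expect_false(tab3$cycle[4] %in% select_cycles(tab3, list(max_if = 18))$cycle)
  # covariate bound and absent-covariate error
  tab4 <- tab
  tab4$speed <- rep(c(0.5, 2), length.out = n)
  expect_equal(
    nrow(select_cycles(tab4, list(min_covariates = list(speed = 1)))),
    sum(tab4$speed >= 1)
  )
  expect_error(
    select_cycles(tab, list(min_covariates = list(speed = 1))),
    "absent covariate"
  )
  expect_error(select_cycles(tab, list(nonsense = 1)), "unknown criteria")
  # idempotence (for criteria with data-independent thresholds)
  crit <- list(amp_floor = 3.5, max_if = 18)
  once <- select_cycles(tab2, crit)
  expect_identical(select_cycles(once, crit), once)
})

test_that("band-to-duration conversion reproduces the published theta bounds", {
  b <- duration_bounds(4, 11, 1250)
  expect_identical(unname(b), c(113, 312))
})
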