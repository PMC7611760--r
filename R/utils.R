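# Low-level signal helpers shared across the package. None of these are
# exported; the user-facing surface lives in the module files.

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state.
# `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Analytic signal via the frequency-domain Hilbert transform: zero out the
# negative frequencies and double the positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 4L, all(is.finite(x)))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# numpy-style phase unwrapping: remove 2*pi jumps from a wrapped angle series.
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1L], d))
}

# Local extrema by strict sign change of the first difference; flat runs
# (plateaus) contribute their midpoint. Returns integer sample indices.
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  d <- diff(x)
  s <- sign(d)
  if (all(s == 0)) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  # carry the last nonzero slope through plateaus so a flat top still counts
  # once, at its midpoint
  last <- 0
  run_start <- NA_integer_
  maxima <- integer(0)
  minima <- integer(0)
  for (i in seq_along(s)) {
    if (s[i] == 0) {
      if (is.na(run_start)) run_start <- i
      next
    }
    if (last != 0 && s[i] != last) {
      # turning point; locate it at the plateau midpoint if one intervened
      if (!is.na(run_start)) {
        idx <- as.integer(floor((run_start + i) / 2))
      } else {
        idx <- i
      }
      if (last > 0) maxima <- c(maxima, idx) else minima <- c(minima, idx)
    }
    last <- s[i]
    run_start <- NA_integer_
  }
  list(maxima = maxima, minima = minima)
}

# Savitzky-Golay smoothing at order 1, window 3: the centered 3-point mean,
# with a shortened one-sided window (2-point mean) at the two boundary samples.
savgol13 <- function(x) {
  n <- length(x)
  if (n < 3L) {
    return(x)
  }
  out <- x
  out[2L:(n - 1L)] <- (x[1L:(n - 2L)] + x[2L:(n - 1L)] + x[3L:n]) / 3
  out[1L] <- (x[1L] + x[2L]) / 2
  out[n] <- (x[n - 1L] + x[n]) / 2
  out
}

# Zero-phase second-order recursive filter with denominator [1, a1, a2]:
# applied forward then backward so the phase response cancels.
filtfilt_ar2 <- function(x, a1, a2) {
  fwd <- stats::filter(x, filter = c(-a1, -a2), method = "recursive")
  rev_in <- rev(as.numeric(fwd))
  bwd <- stats::filter(rev_in, filter = c(-a1, -a2), method = "recursive")
  rev(as.numeric(bwd))
}

# Linear interpolation with linear (not constant) extrapolation beyond the
# observed x range, matching a 1-D interpolator with extrapolate=TRUE.
approx_extrap <- function(x, y, xout) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  out <- stats::approx(x, y, xout = xout, ties = "ordered")$y
  lo <- xout < x[1L]
  hi <- xout > x[length(x)]
  if (any(lo)) {
    slope <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    out[lo] <- y[1L] + slope * (xout[lo] - x[1L])
  }
  if (any(hi)) {
    m <- length(x)
    slope <- (y[m] - y[m - 1L]) / (x[m] - x[m - 1L])
    out[hi] <- y[m] + slope * (xout[hi] - x[m])
  }
  out
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) {
    return(0L)
  }
  sum(diff(s) != 0)
}
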