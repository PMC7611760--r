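#' Empirical mode decomposition: standard and masked sift
#'
#' The sift incrementally extracts the fastest oscillatory component of a
#' signal (an intrinsic mode function, IMF) by repeatedly subtracting the
#' mean of its upper and lower extrema envelopes, then repeats on the
#' residual. The masked variant adds a known sinusoid before extrema
#' detection so that slow components cannot leak into a fast IMF when the
#' fast activity is intermittent (mode mixing); the mask is removed again by
#' subtraction. Envelopes use a monotone piecewise-cubic Hermite (PCHIP)
#' interpolant, which cannot overshoot between extrema the way a natural
#' cubic spline can.
#'
#' @name sift
NULL

#' Monotone (PCHIP) envelope through signal extrema
#'
#' Interpolates extrema values onto every integer sample position with the
#' Fritsch-Carlson monotone Hermite cubic. Before interpolating, the first
#' and last extrema are reflected beyond the signal bounds (about sample 0
#' and sample `n_samples - 1`) to bound envelope behaviour at the edges.
#'
#' @param extrema_positions Strictly increasing sample positions (0-based,
#'   may be fractional) of the extrema.
#' @param extrema_values Signal values at those positions.
#' @param n_samples Length of the envelope to return.
#' @return Numeric vector of length `n_samples`: the envelope at samples
#'   `0 .. n_samples - 1`.
#' @export
interpolate_envelope <- function(extrema_positions, extrema_values, n_samples) {
  p <- as.numeric(extrema_positions)
  v <- as.numeric(extrema_values)
  if (length(p) < 2L) {
    stop("fewer than 2 extrema: signal is a residual trend")
  }
  stopifnot(length(p) == length(v), all(diff(p) > 0), n_samples >= 1L)
  # reflect up to two leading/trailing extrema about the signal bounds
  k <- min(2L, length(p))
  left_p <- -rev(p[seq_len(k)])
  left_v <- rev(v[seq_len(k)])
  keep_l <- left_p < p[1L]
  m <- length(p)
  right_p <- 2 * (n_samples - 1) - rev(p[(m - k + 1L):m])
  right_v <- rev(v[(m - k + 1L):m])
  keep_r <- right_p > p[m]
  xs <- c(left_p[keep_l], p, right_p[keep_r])
  ys <- c(left_v[keep_l], v, right_v[keep_r])
  f <- stats::splinefun(xs, ys, method = "monoH.FC")
  f(seq.int(0L, n_samples - 1L))
}

# Extract one IMF from `x` by the inner sift loop. Returns NULL when `x` has
# too few extrema to sift (it is already a residual trend).
sift_inner <- function(x, stop_threshold = 0.1, max_iter = 15L) {
  h <- x
  n <- length(x)
  for (it in seq_len(max_iter)) {
    ex <- find_extrema(h)
    if (length(ex$maxima) < 2L || length(ex$minima) < 2L) {
      if (it == 1L) {
        return(NULL)
      }
      break
    }
    upper <- interpolate_envelope(ex$maxima - 1L, h[ex$maxima], n)
    lower <- interpolate_envelope(ex$minima - 1L, h[ex$minima], n)
    h_new <- h - (upper + lower) / 2
    sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
    h <- h_new
    if (sd_crit < stop_threshold) break
  }
  h
}

#' Standard sift
#'
#' @param x A `cycleshape_ts`, or a numeric vector with `fs` given.
#' @param max_imfs Maximum number of IMFs to extract.
#' @param stop_threshold Sum-of-squared-differences stopping criterion for
#'   the inner sift (default `0.1`, the classic value). Much smaller
#'   thresholds over-sift: they split a noisy narrowband oscillation across
#'   neighbouring IMFs.
#' @param max_iter Hard cap on inner sift iterations (default 15).
#' @param fs Sampling rate, required only when `x` is a plain vector.
#' @return A `cycleshape_imfs`: list with `imfs` (matrix, one column per
#'   IMF), `residual`, `fs`, and (for masked sifts) `mask_freqs`/`mask_amps`.
#'   IMFs plus residual always reconstruct the input.
#' @export
sift_standard <- function(x, max_imfs = 9L, stop_threshold = 0.1,
                          max_iter = 15L, fs = NULL) {
  ts <- as_timeseries(x, fs)
  if (!all(is.finite(ts$samples))) stop("non-finite values in input")
  stopifnot(length(ts$samples) >= 16L)
  resid <- ts$samples
  imfs <- list()
  for (k in seq_len(max_imfs)) {
    imf <- sift_inner(resid, stop_threshold, max_iter)
    if (is.null(imf)) break
    imfs[[k]] <- imf
    resid <- resid - imf
    ex <- find_extrema(resid)
    if (length(ex$maxima) < 2L || length(ex$minima) < 2L) break
  }
  if (length(imfs) == 0L) stop("input has too few extrema to sift")
  new_imfset(do.call(cbind, imfs), resid, ts$fs)
}

#' Masked sift
#'
#' At each level a sinusoidal mask at the level's frequency is added at
#' `n_phases` evenly spaced phase offsets; one IMF is extracted per offset
#' (inner sift), the mask subtracted, and the level's IMF taken as the mean
#' over offsets. The residual passes to the next level. Averaging over mask
#' phases removes the bias any single mask phase would imprint.
#'
#' @inheritParams sift_standard
#' @param mask_freqs Strictly decreasing mask frequencies in Hz, all below
#'   the Nyquist frequency. One IMF is extracted per mask.
#' @param mask_amp_ratio Mask amplitude as a multiple of the standard
#'   deviation of the current residual (default 2), used when `mask_amps` is
#'   not given.
#' @param n_phases Number of evenly spaced mask phase offsets to average
#'   over (default 4).
#' @param mask_amps Optional explicit mask amplitudes (signal units), one
#'   per mask frequency.
#' @export
sift_masked <- function(x, mask_freqs, mask_amp_ratio = 2, n_phases = 4L,
                        mask_amps = NULL, stop_threshold = 0.1,
                        max_iter = 15L, fs = NULL) {
  ts <- as_timeseries(x, fs)
  if (!all(is.finite(ts$samples))) stop("non-finite values in input")
  stopifnot(length(mask_freqs) >= 1L, n_phases >= 1L)
  if (any(mask_freqs >= ts$fs / 2)) {
    stop("mask frequency at or above Nyquist (", ts$fs / 2, " Hz)")
  }
  if (length(mask_freqs) > 1L && any(diff(mask_freqs) >= 0)) {
    stop("mask_freqs must be strictly decreasing")
  }
  if (!is.null(mask_amps)) stopifnot(length(mask_amps) == length(mask_freqs))
  n <- length(ts$samples)
  tt <- seq.int(0L, n - 1L) / ts$fs
  resid <- ts$samples
  imfs <- matrix(0, n, length(mask_freqs))
  amps_used <- numeric(length(mask_freqs))
  offsets <- 2 * pi * (seq_len(n_phases) - 1L) / n_phases
  for (lev in seq_along(mask_freqs)) {
    amp <- if (is.null(mask_amps)) {
      mask_amp_ratio * stats::sd(resid)
    } else {
      mask_amps[lev]
    }
    amps_used[lev] <- amp
    acc <- numeric(n)
    for (ph in offsets) {
      mask <- amp * cos(2 * pi * mask_freqs[lev] * tt + ph)
      imf_ph <- sift_inner(resid + mask, stop_threshold, max_iter)
      if (is.null(imf_ph)) imf_ph <- resid + mask
      acc <- acc + (imf_ph - mask)
    }
    imfs[, lev] <- acc / n_phases
    resid <- resid - imfs[, lev]
  }
  new_imfset(imfs, resid, ts$fs, mask_freqs = mask_freqs, mask_amps = amps_used)
}

#' Derive a halving mask schedule from the data
#'
#' The zero-crossing count of a first standard-sift IMF sets the initial
#' mask frequency (`crossings / (2 * duration)` Hz); each subsequent mask is
#' applied at half the previous frequency, stopping once a mask would fall
#' below one cycle over the recording. Mask amplitudes are set to one
#' standard deviation of the previously extracted IMF, which interleaves
#' schedule derivation with the masked sift itself; the realised schedule is
#' returned together with the decomposition so the same `(freqs, amps)` fed
#' back to [sift_masked()] reproduces it.
#'
#' @inheritParams sift_standard
#' @param n_phases Mask phase offsets per level, as in [sift_masked()].
#' @return A list with `mask_freqs`, `mask_amps`, and `imfset`, the masked
#'   decomposition realised while deriving the amplitudes.
#' @export
derive_mask_schedule <- function(x, n_phases = 4L, stop_threshold = 0.1,
                                 fs = NULL) {
  ts <- as_timeseries(x, fs)
  duration_s <- length(ts$samples) / ts$fs
  first <- sift_inner(ts$samples, stop_threshold)
  if (is.null(first)) stop("too few zero crossings to derive a mask schedule")
  zc <- count_zero_crossings(first)
  if (zc < 2L) stop("too few zero crossings to derive a mask schedule")
  f1 <- zc / (2 * duration_s)
  freqs <- f1
  while (utils::tail(freqs, 1L) / 2 >= 1 / duration_s) {
    freqs <- c(freqs, utils::tail(freqs, 1L) / 2)
  }
  n <- length(ts$samples)
  tt <- seq.int(0L, n - 1L) / ts$fs
  resid <- ts$samples
  imfs <- matrix(0, n, length(freqs))
  amps <- numeric(length(freqs))
  prev_imf <- first
  offsets <- 2 * pi * (seq_len(n_phases) - 1L) / n_phases
  for (lev in seq_along(freqs)) {
    amps[lev] <- stats::sd(prev_imf)
    acc <- numeric(n)
    for (ph in offsets) {
      mask <- amps[lev] * cos(2 * pi * freqs[lev] * tt + ph)
      imf_ph <- sift_inner(resid + mask, stop_threshold)
      if (is.null(imf_ph)) imf_ph <- resid + mask
      acc <- acc + (imf_ph - mask)
    }
    imfs[, lev] <- acc / n_phases
    resid <- resid - imfs[, lev]
    prev_imf <- imfs[, lev]
  }
  list(
    mask_freqs = freqs,
    mask_amps = amps,
    imfset = new_imfset(imfs, resid, ts$fs, mask_freqs = freqs, mask_amps = amps)
  )
}

# --- IMF container ---------------------------------------------------------

new_imfset <- function(imfs, residual, fs, mask_freqs = NULL, mask_amps = NULL) {
  imfs <- as.matrix(imfs)
  colnames(imfs) <- paste0("IMF", seq_len(ncol(imfs)))
  structure(
    list(
      imfs = imfs, residual = as.numeric(residual), fs = fs,
      mask_freqs = mask_freqs, mask_amps = mask_amps
    ),
    class = "cycleshape_imfs"
  )
}

#' Reconstruct the sifted input from an IMF set
#' @param imfset A `cycleshape_imfs`.
#' @return The row-wise sum of all IMFs plus the residual.
#' @export
reconstruct <- function(imfset) {
  stopifnot(inherits(imfset, "cycleshape_imfs"))
  rowSums(imfset$imfs) + imfset$residual
}

#' @export
print.cycleshape_imfs <- function(x, ...) {
  cat(sprintf(
    "<cycleshape_imfs> %d IMFs + residual, %d samples @ %g Hz\n",
    ncol(x$imfs), nrow(x$imfs), x$fs
  ))
  if (!is.null(x$mask_freqs)) {
    cat("  mask schedule (Hz):", paste(signif(x$mask_freqs, 4), collapse = ", "), "\n")
  }
  invisible(x)
}
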