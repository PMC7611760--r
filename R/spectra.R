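#' Instantaneous phase, frequency and amplitude of an IMF
#'
#' Computes the analytic form of an IMF with the Hilbert transform. The
#' instantaneous phase is the complex angle, mapped so that phase 0 falls at
#' the ascending zero-crossing of a sine-like cycle (peak at `pi/2`,
#' descending zero-crossing at `pi`, trough at `3*pi/2`). The unwrapped
#' phase is smoothed with a Savitzky-Golay filter (order 1, window 3
#' samples) to attenuate differentiation noise, and the instantaneous
#' frequency (Hz) is its forward difference scaled by `fs / (2*pi)` (last
#' value repeated to preserve length). Negative frequency values are kept:
#' they flag phase reversals that the cycle quality control later rejects.
#'
#' @param imf Numeric vector (one IMF), length >= 4.
#' @param fs Sampling rate in Hz.
#' @param smooth Apply the phase smoothing (default `TRUE`).
#' @return A `cycleshape_trace`: list with `phase_wrapped` (radians in
#'   `[0, 2*pi)`), `phase_unwrapped`, `if_hz`, `ia`, `signal` (the input
#'   IMF) and `fs`.
#' @export
frequency_transform <- function(imf, fs, smooth = TRUE) {
  x <- as.numeric(imf)
  stopifnot(length(x) >= 4L, fs > 0, all(is.finite(x)))
  if (max(x) - min(x) < .Machine$double.eps * 100) {
    stop("constant input: instantaneous phase undefined")
  }
  z <- analytic_signal(x)
  wrapped <- (Arg(z) + pi / 2) %% (2 * pi)
  unwrapped <- unwrap_phase(wrapped)
  smoothed <- if (smooth) savgol13(unwrapped) else unwrapped
  d <- diff(smoothed)
  if_hz <- fs / (2 * pi) * c(d, d[length(d)])
  structure(
    list(
      phase_wrapped = smoothed %% (2 * pi),
      phase_unwrapped = smoothed,
      if_hz = if_hz,
      ia = Mod(z),
      signal = x,
      fs = fs
    ),
    class = "cycleshape_trace"
  )
}

#' @export
print.cycleshape_trace <- function(x, ...) {
  cat(sprintf(
    "<cycleshape_trace> %d samples @ %g Hz; median IF %.2f Hz\n",
    length(x$if_hz), x$fs, stats::median(x$if_hz)
  ))
  invisible(x)
}

#' Hilbert-Huang transform
#'
#' Builds a time-frequency amplitude matrix by depositing each sample's
#' instantaneous amplitude into the frequency bin containing its
#' instantaneous frequency, summed over IMFs. Bins are half-open
#' `[low, high)`; frequencies outside the edge range are dropped.
#'
#' @param traces A single `cycleshape_trace` or a list of them.
#' @param freq_edges Strictly increasing bin edges in Hz. The default is 64
#'   bins spanning 2-35 Hz.
#' @return A `cycleshape_spectrum`: list with `freq_bins` (bin centers),
#'   `amplitude` (`n_times x n_freqs` matrix) and `fs`.
#' @export
hht <- function(traces, freq_edges = seq(2, 35, length.out = 65L)) {
  if (inherits(traces, "cycleshape_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L, all(diff(freq_edges) > 0))
  n_t <- length(traces[[1L]]$if_hz)
  n_f <- length(freq_edges) - 1L
  amp <- matrix(0, n_t, n_f)
  for (tr in traces) {
    stopifnot(inherits(tr, "cycleshape_trace"), length(tr$if_hz) == n_t)
    bin <- findInterval(tr$if_hz, freq_edges, left.open = FALSE)
    ok <- bin >= 1L & bin <= n_f & tr$if_hz < freq_edges[n_f + 1L]
    idx <- cbind(which(ok), bin[ok])
    amp[idx] <- amp[idx] + tr$ia[ok]
  }
  new_spectrum((freq_edges[-1L] + freq_edges[-(n_f + 1L)]) / 2, amp, traces[[1L]]$fs)
}

#' Continuous Morlet wavelet transform
#'
#' Amplitude of the convolution of the signal with unit-energy complex
#' Morlet atoms (`n_cycles` cycles; Gaussian envelope standard deviation
#' `n_cycles / (2*pi*f)` seconds) at each requested frequency.
#'
#' @param x A `cycleshape_ts`, or numeric vector with `fs` given.
#' @param freqs Analysis frequencies in Hz, all below Nyquist. Default: the
#'   centers of 64 bins spanning 2-35 Hz, matching [hht()].
#' @param n_cycles Cycles per Morlet atom (default 5).
#' @param fs Sampling rate when `x` is a plain vector.
#' @return A `cycleshape_spectrum` of wavelet amplitudes.
#' @export
morlet_transform <- function(x, freqs = NULL, n_cycles = 5, fs = NULL) {
  ts <- as_timeseries(x, fs)
  if (is.null(freqs)) {
    edges <- seq(2, 35, length.out = 65L)
    freqs <- (edges[-1L] + edges[-65L]) / 2
  }
  stopifnot(all(freqs > 0), all(freqs < ts$fs / 2), n_cycles > 0)
  n <- length(ts$samples)
  amp <- matrix(0, n, length(freqs))
  # FFT-based convolution, 'same' alignment, atoms centered
  halves <- ceiling(3 * n_cycles / (2 * pi * freqs) * ts$fs)
  nfft <- stats::nextn(n + 2L * max(halves) + 1L, 2)
  fx <- stats::fft(c(ts$samples, numeric(nfft - n)))
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sd_t <- n_cycles / (2 * pi * f)
    half <- halves[j]
    tt <- seq.int(-half, half) / ts$fs
    atom <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sd_t^2))
    atom <- atom / sqrt(sum(Mod(atom)^2))
    la <- length(atom)
    fa <- stats::fft(c(atom, complex(real = numeric(nfft - la))))
    conv <- stats::fft(fx * fa, inverse = TRUE) / nfft
    amp[, j] <- Mod(conv[(half + 1L):(half + n)])
  }
  new_spectrum(freqs, amp, ts$fs)
}

new_spectrum <- function(freq_bins, amplitude, fs) {
  stopifnot(all(diff(freq_bins) > 0), all(amplitude >= 0))
  structure(
    list(freq_bins = as.numeric(freq_bins), amplitude = amplitude, fs = fs),
    class = "cycleshape_spectrum"
  )
}

#' @export
print.cycleshape_spectrum <- function(x, ...) {
  avg <- colMeans(x$amplitude)
  cat(sprintf(
    "<cycleshape_spectrum> %d times x %d bins (%.2f-%.2f Hz); peak bin %.2f Hz\n",
    nrow(x$amplitude), length(x$freq_bins), min(x$freq_bins), max(x$freq_bins),
    x$freq_bins[which.max(avg)]
  ))
  invisible(x)
}

#' Time-averaged spectrum and its local peaks
#'
#' Convenience accessor: the time-averaged amplitude profile of a spectrum
#' and the bin frequencies of its local maxima, sorted by prominence
#' (amplitude), used e.g. to locate a harmonic above a fundamental.
#'
#' @param spectrum A `cycleshape_spectrum`.
#' @return A list with `freq_bins`, `mean_amplitude`, and `peaks`, a tibble
#'   of local maxima (`freq_hz`, `amplitude`) in decreasing amplitude order.
#' @export
spectrum_peaks <- function(spectrum) {
  stopifnot(inherits(spectrum, "cycleshape_spectrum"))
  avg <- colMeans(spectrum$amplitude)
  ex <- find_extrema(avg)
  pk <- ex$maxima
  ord <- order(avg[pk], decreasing = TRUE)
  list(
    freq_bins = spectrum$freq_bins,
    mean_amplitude = avg,
    peaks = tibble::tibble(
      freq_hz = spectrum$freq_bins[pk][ord],
      amplitude = avg[pk][ord]
    )
  )
}
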