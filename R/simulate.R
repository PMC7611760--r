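#' Simulated oscillatory signals with known waveform shape
#'
#' @description
#' Generators for every synthetic signal used to validate the waveform-shape
#' pipeline: noise-free schematic cycles with prescribed shape distortions,
#' a stochastic autoregressive (AR) oscillator, a quadratic ("Feynman-type")
#' static nonlinearity, and a dynamic-shape signal whose cycles are randomly
#' assigned to known shape categories.
#'
#' All generators are bit-reproducible under a fixed `seed` and never disturb
#' the caller's RNG state.
#'
#' @name simulate-signals
NULL

#' One noise-free cycle with a prescribed nonsinusoidal shape
#'
#' Builds a single oscillatory cycle by modulating a linearly progressing
#' phase time course with a low-order sinusoid and taking the sine of the
#' result. Edge asymmetries (fast ascent / fast descent) use a 1-cycle
#' modulator, extrema-width asymmetries (wide / narrow peak) a phase-shifted
#' 1-cycle modulator, and extrema-curvature shapes (pinched / widened
#' extrema) a 2-cycle modulator. The additive modulation term is
#' `(m/k) * sin(k * phi0 + psi)` so the phase derivative `1 + m*cos(.)`
#' stays strictly positive for every shape whenever `mod_depth < 1`.
#'
#' @param shape One of `"sinusoid"`, `"wide_peak"`, `"narrow_peak"`,
#'   `"fast_ascent"`, `"fast_descent"`, `"pinched_extrema"`,
#'   `"widened_extrema"`.
#' @param n_samples Samples per cycle (>= 32). The nominal cycle frequency is
#'   1 Hz at a sampling rate of `n_samples` Hz.
#' @param mod_depth Peak fractional modulation of the phase velocity, in
#'   `[0, 1)`. `0` gives a pure sinusoid for every shape.
#' @return A list with `waveform` (length `n_samples`, amplitude 1, starting
#'   at the ascending zero-crossing) and `phase` (the modulated phase in
#'   radians, strictly increasing from 0 to just under `2*pi`).
#' @examples
#' cyc <- schematic_cycle("fast_ascent", 512, 0.3)
#' all(diff(cyc$phase) > 0)
#' @export
schematic_cycle <- function(shape, n_samples, mod_depth = 0.3) {
  shapes <- c(
    "sinusoid", "wide_peak", "narrow_peak", "fast_ascent",
    "fast_descent", "pinched_extrema", "widened_extrema"
  )
  if (!is.character(shape) || length(shape) != 1L || !(shape %in% shapes)) {
    stop(
      "unknown shape '", paste(shape, collapse = ","),
      "'; valid shapes: ", paste(shapes, collapse = ", ")
    )
  }
  stopifnot(n_samples >= 32L, mod_depth >= 0, mod_depth < 1)
  phi0 <- 2 * pi * (seq_len(n_samples) - 1L) / n_samples
  m <- mod_depth
  # (k = modulator cycles per cycle, psi = modulator phase). psi places the
  # instantaneous-frequency extremum: IF is maximal where cos(k*phi0+psi)=1.
  par <- switch(shape,
    sinusoid        = c(k = 1, psi = 0, m = 0),
    fast_ascent     = c(k = 1, psi = 0, m = m),          # fastest at phi = 0
    fast_descent    = c(k = 1, psi = pi, m = m),         # fastest at phi = pi
    wide_peak       = c(k = 1, psi = pi / 2, m = m),     # slowest at phi = pi/2
    narrow_peak     = c(k = 1, psi = -pi / 2, m = m),    # fastest at phi = pi/2
    pinched_extrema = c(k = 2, psi = pi, m = m),         # fast at both extrema
    widened_extrema = c(k = 2, psi = 0, m = m)           # slow at both extrema
  )
  k <- par[["k"]]
  psi <- par[["psi"]]
  m <- par[["m"]]
  phase <- phi0 + (m / k) * (sin(k * phi0 + psi) - sin(psi))
  list(waveform = sin(phase), phase = phase)
}

#' Stochastic narrowband oscillation from an autoregressive resonator
#'
#' White Gaussian noise is passed forward and backward (zero phase) through
#' the second-order recursive filter with denominator coefficients
#' `[1, -2 r cos(theta), r^2]`, `theta = 2 pi freq_hz / fs`, producing a
#' noisy oscillation with natural cycle-by-cycle variability in amplitude
#' and frequency. The output is rescaled to unit standard deviation so that
#' absolute amplitude thresholds (e.g. the 0.04 cycle-inclusion floor) are
#' meaningful.
#'
#' @param freq_hz Resonant frequency in Hz (`0 < freq_hz < fs/2`).
#' @param r Pole radius in (0, 1); closer to 1 gives a narrower resonance.
#' @param fs Sampling rate in Hz.
#' @param duration_s Duration in seconds; output length is
#'   `round(duration_s * fs)`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list with `samples`, `fs` and `seed` (a `"cycleshape_ts"`).
#' @export
ar_oscillation <- function(freq_hz, r, fs, duration_s, seed = NULL) {
  stopifnot(r > 0, freq_hz > 0, freq_hz < fs / 2, fs > 0, duration_s > 0)
  if (r >= 1) stop("pole radius r must be < 1 (filter unstable)")
  n <- round(duration_s * fs)
  theta <- 2 * pi * freq_hz / fs
  x <- with_seed(seed, stats::rnorm(n))
  y <- filtfilt_ar2(x, a1 = -2 * r * cos(theta), a2 = r^2)
  y <- y / stats::sd(y)
  new_timeseries(y, fs, seed)
}

#' Static linear or quadratic system applied to an oscillation
#'
#' Implements `x_out = K * (x + epsilon * x^2) + e(t)` with Gaussian noise
#' `e(t)` of standard deviation `noise_sd`. With `epsilon = 0` this is a pure
#' gain (waveform shape unchanged); `epsilon > 0` shortens the peaks and
#' widens the troughs of a zero-mean oscillation, introducing a harmonic at
#' twice the fundamental.
#'
#' @param x A `cycleshape_ts` (or plain numeric vector).
#' @param K Gain.
#' @param epsilon Quadratic coefficient (0 = linear system).
#' @param noise_sd Standard deviation of the additive white noise (>= 0).
#' @param seed Integer seed for the noise, or `NULL`.
#' @return A `cycleshape_ts` with the same sampling rate as the input.
#' @export
apply_feynman_system <- function(x, K = 1, epsilon = 0, noise_sd = 0,
                                 seed = NULL) {
  ts <- if (inherits(x, "cycleshape_ts")) x else new_timeseries(x, fs = 1)
  stopifnot(all(is.finite(ts$samples)), noise_sd >= 0)
  out <- K * (ts$samples + epsilon * ts$samples^2)
  if (noise_sd > 0) {
    out <- out + with_seed(seed, stats::rnorm(length(out), sd = noise_sd))
  }
  new_timeseries(out, ts$fs, seed)
}

#' Oscillation whose cycles switch between known shape categories
#'
#' Generates an AR oscillation, estimates its Hilbert phase, segments the
#' phase into cycles, assigns each complete cycle independently and uniformly
#' at random to `"sinusoidal"`, `"fast_ascending"` or `"fast_descending"`,
#' modulates the phase of the nonsinusoidal cycles with an additive
#' within-cycle sinusoid (as in [schematic_cycle()]), re-synthesises the
#' signal as the sine of the modulated phase carrying the original amplitude
#' envelope, and finally adds Gaussian noise.
#'
#' @inheritParams ar_oscillation
#' @param mod_depth Peak fractional phase-velocity modulation of the
#'   nonsinusoidal cycles (default 0.3).
#' @param noise_sd Standard deviation of the additive Gaussian noise. The
#'   default, `NULL`, uses 0.2 x the standard deviation of the noiseless
#'   re-synthesised oscillation.
#' @param preserve_envelope Keep the AR amplitude envelope (default) or
#'   synthesise at unit amplitude. Preserving the envelope lets the
#'   amplitude-based cycle quality controls reject noise-dominated periods.
#' @param r Pole radius of the underlying oscillator (default 0.99). The
#'   dynamic-shape generator needs a coherent oscillation so that imposed
#'   shape differences, not cycle-frequency variability, dominate the
#'   between-cycle variance; see the methods vignette.
#' @return A list with `signal` (a `cycleshape_ts`), `clean` (the noiseless
#'   re-synthesised oscillation) and `labels`, a tibble with `cycle_index`,
#'   `category`, and the cycle's sample bounds `start`/`end` (0-based,
#'   half-open).
#' @export
dynamic_shape_signal <- function(freq_hz, fs, duration_s, mod_depth = 0.3,
                                 noise_sd = NULL, seed = NULL, r = 0.99,
                                 preserve_envelope = TRUE) {
  base <- ar_oscillation(freq_hz, r, fs, duration_s,
    seed = if (is.null(seed)) NULL else seed
  )
  z <- analytic_signal(base$samples)
  ia <- Mod(z)
  # phase convention: 0 at the ascending zero-crossing, peak at pi/2
  wrapped <- (Arg(z) + pi / 2) %% (2 * pi)
  unwrapped <- unwrap_phase(wrapped)
  # cycle boundaries at the phase wrap (large negative jump in wrapped phase)
  bounds <- which(diff(wrapped) < -6) + 1L
  if (length(bounds) < 2L) {
    stop("duration too short: no complete cycle in the generated oscillation")
  }
  n_cycles <- length(bounds) - 1L
  categories <- c("sinusoidal", "fast_ascending", "fast_descending")
  draws <- with_seed(
    if (is.null(seed)) NULL else seed + 1L,
    sample(categories, n_cycles, replace = TRUE)
  )
  phase_mod <- unwrapped
  for (ci in seq_len(n_cycles)) {
    idx <- bounds[ci]:(bounds[ci + 1L] - 1L)
    # rebuild the cycle on a linear base phase (0..2*pi over the cycle's own
    # duration), exactly as the schematic cycles are built: duration and
    # amplitude variability survive, within-cycle phase jitter does not
    w <- 2 * pi * (seq_along(idx) - 1L) / length(idx)
    base <- unwrapped[bounds[ci]] - wrapped[bounds[ci]]
    sgn <- switch(draws[ci],
      sinusoidal = 0,
      fast_ascending = 1,
      fast_descending = -1
    )
    # additive sinusoid of the local phase; vanishes at the cycle boundaries
    # so the modulated phase stays continuous
    phase_mod[idx] <- base + w + sgn * mod_depth * sin(w)
  }
  clean <- sin(phase_mod)
  if (preserve_envelope) clean <- ia * clean
  if (is.null(noise_sd)) noise_sd <- 0.2 * stats::sd(clean)
  noisy <- clean
  if (noise_sd > 0) {
    noisy <- clean + with_seed(
      if (is.null(seed)) NULL else seed + 2L,
      stats::rnorm(length(clean), sd = noise_sd)
    )
  }
  labels <- tibble::tibble(
    cycle_index = seq_len(n_cycles),
    category = draws,
    start = bounds[-length(bounds)] - 1L,
    end = bounds[-1L] - 1L
  )
  list(
    signal = new_timeseries(noisy, fs, seed),
    clean = new_timeseries(clean, fs, seed),
    labels = labels
  )
}

# --- time-series container -------------------------------------------------

new_timeseries <- function(samples, fs, seed = NULL) {
  stopifnot(fs > 0, length(samples) >= 2L, all(is.finite(samples)))
  structure(
    list(samples = as.numeric(samples), fs = fs, seed = seed),
    class = "cycleshape_ts"
  )
}

as_timeseries <- function(x, fs = NULL) {
  if (inherits(x, "cycleshape_ts")) {
    return(x)
  }
  if (is.null(fs)) stop("a plain vector needs an explicit sampling rate `fs`")
  new_timeseries(x, fs)
}

#' @export
print.cycleshape_ts <- function(x, ...) {
  cat(sprintf(
    "<cycleshape_ts> %d samples @ %g Hz (%.2f s)\n",
    length(x$samples), x$fs, length(x$samples) / x$fs
  ))
  invisible(x)
}
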