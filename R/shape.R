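#' Phase-aligned instantaneous frequency profiles and shape summaries
#'
#' Phase-alignment re-registers each cycle's instantaneous frequency (IF)
#' from its own phase time course onto a fixed uniform phase grid, removing
#' cycle-to-cycle differences in duration and internal timing so whole
#' waveform profiles can be averaged and compared. The grid has 48 points
#' across 0..2*pi, placed at bin centers `2*pi*(k + 1/2)/48`, k = 0..47.
#'
#' @name shape
NULL

#' The uniform phase grid used for alignment
#' @param n_bins Number of grid points (default 48).
#' @return Numeric vector of grid phases in radians.
#' @export
phase_grid <- function(n_bins = 48L) {
  stopifnot(n_bins >= 4L)
  2 * pi * (seq_len(n_bins) - 0.5) / n_bins
}

#' Phase-align one cycle's instantaneous frequency profile
#'
#' Fits a linear one-dimensional interpolant with the cycle's wrapped
#' instantaneous phase as x and its instantaneous frequency as y, and
#' evaluates it at the grid phases; grid points outside the observed phase
#' range receive linearly extrapolated values.
#'
#' @param trace A `cycleshape_trace`.
#' @param cycle Length-2 vector `c(start, end)`: 0-based half-open sample
#'   bounds of a good cycle (monotone phase).
#' @param n_bins Grid size (default 48).
#' @return Numeric vector of length `n_bins`: IF in Hz on the phase grid.
#' @export
phase_align <- function(trace, cycle, n_bins = 48L) {
  stopifnot(inherits(trace, "cycleshape_trace"), length(cycle) == 2L)
  idx <- (cycle[1L] + 1L):cycle[2L]
  ph <- trace$phase_wrapped[idx]
  if (any(diff(ph) <= 0)) {
    stop("non-monotone phase within cycle: interpolation ill-posed")
  }
  approx_extrap(ph, trace$if_hz[idx], phase_grid(n_bins))
}

#' Phase-align every cycle in a table
#'
#' @param trace A `cycleshape_trace`.
#' @param table A cycle tibble (e.g. from [select_cycles()]); only rows with
#'   `good = TRUE` are aligned.
#' @param n_bins Grid size (default 48).
#' @return A `cycleshape_profiles`: list with `grid` (phases), `profiles`
#'   (`n_bins x n_cycles` matrix of IF in Hz) and `cycle_ids` (the `cycle`
#'   column of the aligned rows).
#' @export
align_cycles <- function(trace, table, n_bins = 48L) {
  tab <- table[table$good, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no good cycles to align")
  profs <- vapply(
    seq_len(nrow(tab)),
    function(i) phase_align(trace, c(tab$start[i], tab$end[i]), n_bins),
    numeric(n_bins)
  )
  new_profiles(
    matrix(profs, nrow = n_bins),
    cycle_ids = tab$cycle, n_bins = n_bins
  )
}

new_profiles <- function(profiles, cycle_ids = NULL, n_bins = nrow(profiles)) {
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) == n_bins, all(is.finite(profiles)))
  if (is.null(cycle_ids)) cycle_ids <- seq_len(ncol(profiles))
  structure(
    list(grid = phase_grid(n_bins), profiles = profiles, cycle_ids = cycle_ids),
    class = "cycleshape_profiles"
  )
}

#' @export
print.cycleshape_profiles <- function(x, ...) {
  cat(sprintf(
    "<cycleshape_profiles> %d phase bins x %d cycles; grand mean IF %.2f Hz\n",
    nrow(x$profiles), ncol(x$profiles), mean(x$profiles)
  ))
  invisible(x)
}

#' Reconstruct a unit-amplitude normalized waveform from an IF profile
#'
#' The IF profile is converted back from hertz to per-bin phase increments:
#' each of the 48 bins advances the phase by `2*pi/48` and lasts a time
#' proportional to `1 / IF`. The phase time course is rebuilt by cumulative
#' summation on a unit time axis and the waveform is its sine, sampled at
#' `n_out` uniform time points. The result has amplitude 1, starts at the
#' ascending zero-crossing, and carries shape information only (duration
#' and amplitude are normalized away).
#'
#' @param profile IF profile (Hz) on the phase grid; must be strictly
#'   positive.
#' @param n_out Output length (default 480, ten samples per phase bin).
#' @return Numeric vector of length `n_out`.
#' @export
normalized_waveform <- function(profile, n_out = 480L) {
  p <- as.numeric(profile)
  if (any(p <= 0)) stop("nonpositive IF in profile: cannot invert to time")
  n <- length(p)
  dt <- (1 / p)
  t_knots <- c(0, cumsum(dt) / sum(dt)) # n + 1 knots on a unit time axis
  ph_knots <- 2 * pi * (0:n) / n
  tt <- seq.int(0L, n_out - 1L) / n_out
  sin(stats::approx(t_knots, ph_knots, xout = tt, ties = "ordered")$y)
}

#' Instantaneous-frequency mean vector of a profile
#'
#' The complex mean over the phase grid of `IF * exp(1i * phase)`. A flat
#' (sinusoidal) profile gives exactly 0; the real part measures
#' ascending-vs-descending edge asymmetry (positive = faster ascending
#' edge) and the imaginary part peak-vs-trough asymmetry.
#'
#' @param profile IF profile (Hz) on the phase grid.
#' @return A single complex value.
#' @export
if_mean_vector <- function(profile) {
  p <- as.numeric(profile)
  stopifnot(all(is.finite(p)))
  mean(p * exp(1i * phase_grid(length(p))))
}

#' Temporally aligned (non-phase-aligned) cycle average
#'
#' Averages cycles locked to their starting sample, over however many
#' cycles are still active at each lag; provided for comparison with the
#' phase-aligned average (temporal alignment blurs shape when cycle
#' durations vary).
#'
#' @param values Numeric vector to average (e.g. `trace$if_hz` or
#'   `trace$signal`).
#' @param table Cycle tibble; rows with `good = TRUE` are used.
#' @return A tibble with `lag` (samples from cycle start), `mean`, and
#'   `n_cycles` contributing at each lag.
#' @export
time_locked_average <- function(values, table) {
  tab <- table[table$good, , drop = FALSE]
  stopifnot(nrow(tab) >= 1L)
  max_len <- max(tab$duration_samples)
  acc <- numeric(max_len)
  cnt <- integer(max_len)
  for (i in seq_len(nrow(tab))) {
    idx <- (tab$start[i] + 1L):tab$end[i]
    L <- length(idx)
    acc[1:L] <- acc[1:L] + values[idx]
    cnt[1:L] <- cnt[1:L] + 1L
  }
  tibble::tibble(lag = 0:(max_len - 1L), mean = acc / cnt, n_cycles = cnt)
}
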