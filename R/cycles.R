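#' Cycle detection, quality control and control-point shape ratios
#'
#' A cycle runs from one ascending zero-crossing to the next, located where
#' the wrapped instantaneous phase jumps back through zero (a first
#' difference below -6 rad, i.e. the 2*pi wrap). Because the Hilbert
#' transform returns a phase for every sample whether or not a rhythm is
#' present, only "good" cycles are retained for shape analysis: strictly
#' increasing phase (no reversals), a phase span covering essentially the
#' whole 0..2*pi range, and exactly one of each control point (peak,
#' descending zero-crossing, trough) between the ascending-zero endpoints.
#'
#' @name cycles
NULL

#' Detect and quality-control cycles in an analytic trace
#'
#' @param trace A `cycleshape_trace` from [frequency_transform()].
#' @return A tibble with one row per detected cycle: `cycle` (index),
#'   `start`/`end` (0-based half-open sample bounds), `good`,
#'   `duration_samples`, `max_ia`, `if_mean`, `if_max`, `if_std` (standard
#'   deviation of interior instantaneous frequency), sub-sample control
#'   points (`asc_start`, `peak`, `desc`, `trough`, `asc_end`; `NA` for bad
#'   cycles) and the shape ratios `p2t_ratio`, `a2d_ratio`. Incomplete
#'   cycles at the recording edges are excluded.
#' @export
detect_cycles <- function(trace) {
  stopifnot(inherits(trace, "cycleshape_trace"))
  w <- trace$phase_wrapped
  wraps <- which(diff(w) < -6) + 1L
  n_cyc <- length(wraps) - 1L
  empty <- tibble::tibble(
    cycle = integer(0), start = integer(0), end = integer(0),
    good = logical(0), duration_samples = integer(0), max_ia = numeric(0),
    if_mean = numeric(0), if_max = numeric(0), if_std = numeric(0),
    asc_start = numeric(0), peak = numeric(0), desc = numeric(0),
    trough = numeric(0), asc_end = numeric(0),
    p2t_ratio = numeric(0), a2d_ratio = numeric(0)
  )
  if (n_cyc < 1L) {
    return(empty)
  }
  rows <- vector("list", n_cyc)
  for (ci in seq_len(n_cyc)) {
    s <- wraps[ci]
    e <- wraps[ci + 1L] # half-open [s, e)
    idx <- s:(e - 1L)
    wc <- w[idx]
    good <- all(diff(trace$phase_unwrapped[s:e]) > 0) &&
      wc[1L] >= 0 && wc[1L] <= pi / 24 &&
      wc[length(wc)] >= 2 * pi - pi / 24 && wc[length(wc)] < 2 * pi
    cp <- list(
      asc_start = NA_real_, peak = NA_real_, desc = NA_real_,
      trough = NA_real_, asc_end = NA_real_
    )
    p2t <- NA_real_
    a2d <- NA_real_
    if (good) {
      cpr <- tryCatch(
        control_points_and_ratios(trace$signal, c(s - 1L, e - 1L)),
        error = function(e) NULL
      )
      if (is.null(cpr)) {
        good <- FALSE
      } else {
        cp <- cpr$control
        p2t <- cpr$p2t_ratio
        a2d <- cpr$a2d_ratio
      }
    }
    interior <- if (length(idx) > 4L) idx[-c(1L, length(idx))] else idx
    rows[[ci]] <- tibble::tibble(
      cycle = ci, start = s - 1L, end = e - 1L, good = good,
      duration_samples = e - s,
      max_ia = max(trace$ia[idx]),
      if_mean = mean(trace$if_hz[idx]),
      if_max = max(trace$if_hz[idx]),
      if_std = stats::sd(trace$if_hz[interior]),
      asc_start = cp$asc_start, peak = cp$peak, desc = cp$desc,
      trough = cp$trough, asc_end = cp$asc_end,
      p2t_ratio = p2t, a2d_ratio = a2d
    )
  }
  do.call(rbind, rows)
}

#' Sub-sample control points and duration ratios for one cycle
#'
#' Extrema are refined to a point between samples by fitting a parabola
#' through the extremum sample and its two neighbours (vertex offset
#' `(y_minus - y_plus) / (2 * (y_minus - 2*y0 + y_plus))`); zero-crossings
#' are refined by linear interpolation between the bracketing samples. The
#' peak-to-trough ratio is the fraction of the cycle during which the
#' signal is positive, `(desc - asc_start) / (asc_end - asc_start)`; the
#' ascent-to-descent ratio is the ascending fraction,
#' `1 - (trough - peak) / (asc_end - asc_start)`. Both equal 0.5 for a
#' sinusoid.
#'
#' @param imf Numeric vector: the IMF the cycle lives in.
#' @param cycle Length-2 vector `c(start, end)`: 0-based half-open sample
#'   bounds of the cycle (from [detect_cycles()]).
#' @return A list with `control` (named list `asc_start`, `peak`, `desc`,
#'   `trough`, `asc_end`, 0-based fractional sample positions, strictly
#'   ordered), `p2t_ratio` and `a2d_ratio`.
#' @export
control_points_and_ratios <- function(imf, cycle) {
  stopifnot(length(cycle) == 2L, cycle[2L] > cycle[1L])
  s <- as.integer(cycle[1L]) + 1L # to 1-based
  e <- as.integer(cycle[2L]) + 1L
  n <- length(imf)
  if (s < 2L || e >= n) stop("cycle touches the recording edge")
  # For nonsinusoidal cycles the Hilbert phase wrap can sit a few samples
  # away from the waveform's ascending zero-crossing, so scan a small margin
  # beyond the phase-derived bounds.
  margin <- max(2L, ceiling(0.06 * (e - s)))
  lo <- max(1L, s - margin)
  hi <- min(e + margin, n)
  seg <- imf[lo:hi]
  off <- lo - 1L # segment index i corresponds to 0-based sample off + i - 1
  asc <- which(seg[-length(seg)] < 0 & seg[-1L] >= 0)
  des <- which(seg[-length(seg)] > 0 & seg[-1L] <= 0)
  zc_refine <- function(i) {
    off + (i - 1L) + seg[i] / (seg[i] - seg[i + 1L])
  }
  ex_refine <- function(i) {
    ym <- seg[i - 1L]
    y0 <- seg[i]
    yp <- seg[i + 1L]
    denom <- ym - 2 * y0 + yp
    d <- if (abs(denom) < .Machine$double.eps) 0 else (ym - yp) / (2 * denom)
    off + (i - 1L) + d
  }
  # the ascending crossings nearest each phase-derived bound delimit the cycle
  if (length(asc) < 2L) stop("cycle lacks a unique set of control points")
  i_start <- asc[which.min(abs(asc - (s - off)))]
  i_end <- asc[which.min(abs(asc - (e - off)))]
  if (i_end <= i_start ||
    abs(i_start - (s - off)) > margin + 1L ||
    abs(i_end - (e - off)) > margin + 1L ||
    sum(asc > i_start & asc < i_end) > 0L) {
    stop("cycle lacks a unique set of control points")
  }
  ex <- find_extrema(seg)
  # interior extrema only (refinement needs both neighbours), within the cycle
  maxi <- ex$maxima[ex$maxima > i_start & ex$maxima <= i_end &
    ex$maxima > 1L & ex$maxima < length(seg)]
  mini <- ex$minima[ex$minima > i_start & ex$minima <= i_end &
    ex$minima > 1L & ex$minima < length(seg)]
  des_in <- des[des > i_start & des < i_end]
  if (length(des_in) != 1L || length(maxi) != 1L || length(mini) != 1L) {
    stop("cycle lacks a unique set of control points")
  }
  asc_start <- zc_refine(i_start)
  asc_end <- zc_refine(i_end)
  peak <- ex_refine(maxi)
  trough <- ex_refine(mini)
  desc <- zc_refine(des_in)
  pts <- c(asc_start, peak, desc, trough, asc_end)
  if (any(diff(pts) <= 0)) stop("control points out of order")
  dur <- asc_end - asc_start
  list(
    control = list(
      asc_start = asc_start, peak = peak, desc = desc,
      trough = trough, asc_end = asc_end
    ),
    p2t_ratio = (desc - asc_start) / dur,
    a2d_ratio = 1 - (trough - peak) / dur
  )
}

#' Filter a cycle table by inclusion criteria
#'
#' Keeps cycles passing the good-cycle flag plus any of: duration bounds
#' (`min_duration`/`max_duration`, samples), an absolute amplitude floor
#' (`amp_floor`, on `max_ia`), an amplitude-percentile floor
#' (`amp_percentile`, fraction in `[0, 1)`: e.g. 0.1 removes the bottom 10%
#' of the amplitude distribution of good cycles), a within-cycle maximum
#' instantaneous frequency ceiling (`max_if`, Hz), and minimum covariate
#' values (`min_covariates`, a named list checked against columns of
#' `table`). Filtering is idempotent.
#'
#' @param table A cycle tibble from [detect_cycles()] (possibly with extra
#'   covariate columns).
#' @param criteria Named list of bounds; unnamed entries are an error.
#' @return The filtered cycle tibble.
#' @export
select_cycles <- function(table, criteria = list()) {
  known <- c(
    "min_duration", "max_duration", "amp_floor", "amp_percentile",
    "max_if", "min_covariates"
  )
  bad <- setdiff(names(criteria), known)
  if (length(bad) || (length(criteria) && is.null(names(criteria)))) {
    stop("unknown criteria: ", paste(bad, collapse = ", "))
  }
  keep <- table$good
  if (!is.null(criteria$min_duration)) {
    keep <- keep & table$duration_samples >= criteria$min_duration
  }
  if (!is.null(criteria$max_duration)) {
    keep <- keep & table$duration_samples <= criteria$max_duration
  }
  if (!is.null(criteria$amp_floor)) {
    keep <- keep & table$max_ia > criteria$amp_floor
  }
  if (!is.null(criteria$amp_percentile)) {
    floor_val <- stats::quantile(table$max_ia[table$good],
      probs = criteria$amp_percentile, names = FALSE, type = 7
    )
    keep <- keep & table$max_ia >= floor_val
  }
  if (!is.null(criteria$max_if)) {
    keep <- keep & table$if_max < criteria$max_if
  }
  for (nm in names(criteria$min_covariates)) {
    if (!nm %in% names(table)) {
      stop("criterion references absent covariate '", nm, "'")
    }
    keep <- keep & table[[nm]] >= criteria$min_covariates[[nm]]
  }
  table[keep & !is.na(keep), , drop = FALSE]
}

#' Convert a frequency band to cycle-duration bounds in samples
#'
#' A band of `lo_hz`-`hi_hz` corresponds to cycle durations between
#' `fs / hi_hz` and `fs / lo_hz` samples (e.g. 4-11 Hz at 1250 Hz gives
#' 113-312 samples).
#'
#' @param lo_hz,hi_hz Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return Named vector `c(min_duration, max_duration)` in samples.
#' @export
duration_bounds <- function(lo_hz, hi_hz, fs) {
  stopifnot(lo_hz > 0, hi_hz > lo_hz, fs > 0)
  c(min_duration = floor(fs / hi_hz), max_duration = floor(fs / lo_hz))
}
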