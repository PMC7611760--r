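---
title: "Quantifying single-cycle waveform shape with phase-aligned instantaneous frequency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cycle waveform shape with phase-aligned instantaneous frequency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycleshape)
```

## The problem and the model

Neuronal oscillations — hippocampal theta is the motivating example — are
rarely sinusoidal. A cycle can rise faster than it falls, carry a wide peak
and a pinched trough, and change that shape from one cycle to the next.
Classical spectral methods either need long windows (bispectra) or reduce a
cycle to a handful of control points. This package implements a framework
that describes the *entire* waveform of *each individual cycle*:

1. **Isolate the oscillation** from the broadband recording with a masked
   empirical mode decomposition (EMD). The sift iteratively subtracts the
   mean of the upper and lower extrema envelopes until an intrinsic mode
   function (IMF) remains; a sinusoidal "mask" added before extrema
   detection prevents slower components from invading a faster IMF when the
   fast activity is intermittent (mode mixing). Envelopes use the monotone
   PCHIP interpolant (`stats::splinefun(method = "monoH.FC")`), which
   cannot overshoot between extrema the way a natural cubic spline can.
2. **Estimate instantaneous phase, frequency and amplitude** of the
   oscillation's IMF with the Hilbert transform. The phase convention puts
   0 at the ascending zero-crossing, the peak at $\pi/2$, the descending
   zero-crossing at $\pi$ and the trough at $3\pi/2$. The unwrapped phase
   is smoothed with a Savitzky–Golay filter (order 1, window 3 samples) and
   the instantaneous frequency (IF) is its forward difference scaled by
   $f_s/2\pi$. Any nonsinusoidal feature appears as a *within-cycle IF
   modulation*: a wide peak is a low-IF interval around $\pi/2$, a fast
   ascending edge is a high-IF interval around 0.
3. **Detect and quality-control cycles**. Cycle bounds sit at the phase
   wrap (first difference of wrapped phase below $-6$ rad). A *good* cycle
   has strictly increasing phase, starts within $[0, \pi/24]$, ends within
   $[2\pi - \pi/24, 2\pi)$, and contains exactly one peak, one trough and
   one descending zero-crossing. Extrema are refined between samples by
   parabolic interpolation, zero-crossings by linear interpolation, giving
   the peak-to-trough ratio (fraction of the cycle spent positive) and
   ascent-to-descent ratio (ascending fraction); both are exactly 0.5 for
   a sinusoid.
4. **Phase-align** each good cycle's IF onto a fixed 48-point phase grid by
   linear interpolation of (phase, IF) pairs, with linear extrapolation at
   the grid edges. This removes duration and internal-timing differences so
   whole profiles can be averaged and compared. A profile can be rendered
   back as a unit-amplitude **normalized waveform** (per-bin duration
   $\propto 1/\mathrm{IF}$, phase rebuilt by cumulative summation, waveform
   = sine of phase), and summarised by the **IF mean vector**
   $\overline{\mathrm{IF} \cdot e^{i\bar\phi}}$ — exactly 0 for a flat
   profile, with the real part measuring edge asymmetry and the imaginary
   part peak/trough asymmetry.
5. **Shape motifs**: PCA across cycles of the $48 \times n$ profile matrix.
   Components ("motifs") are eigenvectors of the phase-by-phase covariance;
   scores say how much of each motif a cycle expresses; exemplar profiles
   project the extreme observed scores back into profile space. Split-half
   resampling assesses reproducibility.
6. **Association with covariates**: one ordinary-least-squares model per
   motif, intercept plus z-scored covariates (population SD), with
   row-shuffle permutation inference — only the covariate under test is
   shuffled, the rest of the design held fixed; two-tailed p-values use the
   $+1$ correction and the published defaults (5000 permutations,
   $\alpha = 0.01$).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `stop_threshold` (inner sift) | 0.1 | – | Classic sum-of-squared-differences criterion. Much smaller values (e.g. `1e-8`) keep iterating to the 15-iteration cap and *over-sift*: a noisy narrowband oscillation gets split across neighbouring IMFs instead of staying in one. With 0.1 the 12-Hz benchmark oscillation lands intact in IMF-3, as expected for the derived mask schedule. |
| `max_iter` (inner sift) | 15 | – | Bounds runtime. The strict IMF property (extrema and zero-crossing counts within 1) is only reached at full convergence (`stop_threshold ~ 1e-10`, `max_iter ~ 75`); the defaults deliberately trade that formal property for oscillation integrity. |
| `mask_amp_ratio` | 2 | × SD of residual | Masks must dominate slower components to pin extrema spacing. Used when explicit amplitudes are not given. |
| mask amplitudes (derived schedule) | 1 × SD of previous IMF | signal units | The published recipe for simulation analyses. These *weak* masks matter: a strong mask between an oscillation and its first harmonic strips the harmonic into its own IMF, i.e. sinusoidalises the cycles and erases the shape signal. The weak schedule keeps fundamental and harmonic together. |
| `n_phases` | 4 | – | Mask phase offsets averaged per level; removes mask-phase bias. |
| good-cycle phase windows | $\pi/24$ | rad | Published inclusion rule. Note at coarse sampling (few samples per cycle) the first sample after the wrap can fall beyond $\pi/24$ by discretisation alone; such cycles are dropped, which thins the sample without biasing shape. |
| `n_bins` (phase grid) | 48 | – | Published grid size; grid points at bin centres $2\pi(k+\tfrac12)/48$ so the wrap itself is never a grid point. |
| `amp_floor`, `max_if` | 0.04, 18 Hz | signal units, Hz | Published simulation inclusion criteria. The AR generator normalises its output to unit SD so the absolute floor has a stable meaning. |
| `n_comp` | 4 | – | Number of retained motifs (the published analyses keep four); a user setting, not a variance target. |
| `n_perm`, `alpha` | 5000, 0.01 | – | Published inference settings. |

## What the simulations emulate — and what they do not

`schematic_cycle()` builds noise-free single cycles by modulating a linear
phase ramp with a sinusoid: a 1-cycle modulator shifts speed between edges
or extrema (fast ascent/descent, wide/narrow peak), a 2-cycle modulator
changes extrema curvature (pinched/widened). The modulator amplitude is
`mod_depth / k` radians for a `k`-cycle modulator, so the phase velocity is
$1 + m\cos(\cdot)$ and stays positive for every shape whenever
`mod_depth < 1` — one bound enforces monotonicity everywhere. A constant is
subtracted so every cycle starts exactly at the ascending zero-crossing.

`ar_oscillation()` filters white Gaussian noise forward and backward through
a second-order resonator (denominator $[1, -2r\cos\theta, r^2]$), giving a
narrowband oscillation with natural amplitude and frequency variability,
rescaled to unit SD.

`apply_feynman_system()` applies the static system
$x_{out} = K[x + \epsilon x^2] + e(t)$. With $\epsilon > 0$ the quadratic
term shortens peaks and widens troughs and puts a harmonic at twice the
fundamental. Defaults $K = 1$, $\epsilon = 0.25$: large enough for a clear
harmonic, small enough that the transfer stays monotone over the signal's
range (at unit SD, $\epsilon \ge 0.5$ starts folding deep troughs). The
noise term's SD is unspecified in the source analyses; 0.2 × the signal SD
is used throughout as a visible but non-destructive floor.

`dynamic_shape_signal()` assigns each cycle of an AR oscillation uniformly
to *sinusoidal*, *fast ascending* or *fast descending*, rebuilds each cycle
on a **linear** phase ramp of its own duration (the same construction as the
schematic cycles), applies the category's phase modulation, re-synthesises
as the sine of the modulated phase carrying the original amplitude envelope,
and adds Gaussian noise. Three deliberate choices:

* **Linearised base phase.** Modulating the raw Hilbert phase instead
  carries the oscillator's within-cycle phase jitter into every category,
  and that jitter — not the imposed shape — then dominates the profile
  variance. Rebuilding on a linear ramp keeps duration and amplitude
  variability while making the assigned category the cycle's actual shape.
* **Pole radius `r = 0.99`** (the static simulations use the published
  0.95). The dynamic generator needs a coherent oscillation: at `r = 0.95`
  the spread of per-cycle frequency (±2 Hz around 12 Hz) exceeds the
  shape-modulation variance for any monotone modulation depth, so the first
  principal component of the aligned profiles is a cycle-*frequency* mode
  rather than the fast-ascending/fast-descending shape continuum the
  simulation exists to create. At 0.99 the shape continuum dominates PC-1,
  the oscillation still shows realistic amplitude dynamics, and the
  benchmark behaviours (oscillation in IMF-3; PC-1 scores tracking the
  ascent-to-descent ratio) all hold.
* **Envelope preserved** (unit-amplitude synthesis is available via
  `preserve_envelope = FALSE`). Keeping the envelope lets the amplitude
  quality controls reject noise-dominated stretches; unit amplitude admits
  them and degrades every downstream shape estimate.

What a green test on these simulations does **not** establish: performance
on real LFP (1/f background, movement artefacts, non-stationary theta
frequency), multichannel consistency, or behaviour of the mask schedule on
spectra with several strong rhythms — the fixed LFP-style schedule
(350, 200, 70, 40, 30, 7, 1 Hz) exists precisely because the derived
halving schedule is a simulation convenience.

## Numerical choices

* Hilbert transform via FFT; phase unwrapped numpy-style; IF by forward
  difference with the last value repeated; negative IF values are kept (they
  mark phase reversals for the cycle QC to reject).
* Savitzky–Golay order 1 window 3 reduces to a centred 3-point mean with a
  2-point one-sided mean at the boundaries.
* Envelope edges: the two outermost extrema on each side are reflected
  about the signal bounds before interpolation.
* Extrema on plateaus take the plateau midpoint; parabolic refinement
  degenerates gracefully (offset 0) when the curvature vanishes.
* Control points: because the Hilbert phase wrap of a strongly
  nonsinusoidal cycle can sit a few samples away from the waveform's
  ascending zero-crossing, the control-point search scans a margin of 6% of
  the cycle length beyond the phase-derived bounds and takes the ascending
  crossings nearest each bound; uniqueness of the interior peak, trough and
  descending crossing is still required.
* Instantaneous-frequency estimates of phase modulation at the carrier rate
  are intrinsically attenuated (the analytic signal blends the carrier with
  its harmonics; for `mod_depth = 0.3` roughly half the imposed modulation
  is recovered). Both the profiles and the control-point ratios see the same
  attenuated waveform, so comparisons between them remain consistent.
* HHT bins are half-open `[low, high)`; values at or above the top edge are
  dropped. Morlet atoms are unit-energy normalised, so amplitude across
  frequencies has a $1/\sqrt{f}$ tilt; peak *frequencies* are unaffected.
* PCA is an explicit eigendecomposition of the 48 × 48 covariance;
  component sign is fixed by the largest-loading-positive rule so refits
  (and column permutations) are bit-identical. Profiles are centred but not
  variance-scaled, preserving the Hz interpretation of components.
* Permutation p-values use $(1 + \#\{|t^*| \ge |t|\})/(1 + n_{perm})$ and
  are therefore never exactly zero; each regressor is tested against its
  own null (the critical value is not pooled across regressors).
* Percentile-based amplitude floors are computed from the good cycles of
  the table passed in; re-filtering an already-filtered table with a
  percentile criterion therefore tightens it (absolute criteria are
  idempotent).

## Known limitations

* The derived halving mask schedule is sensitive to where its grid lands
  relative to the oscillation and its harmonic; for real recordings a fixed,
  hand-chosen schedule (as in the LFP analyses) is the robust choice.
* Shape recovery degrades when the additive noise approaches the
  oscillation's amplitude; the QC then rejects most cycles rather than
  returning biased shapes.
* Cycle-level inference assumes cycles are exchangeable units; no
  correction for temporal autocorrelation across neighbouring cycles is
  applied (matching the published analyses).
* Only IF profiles are phase-aligned; amplitude-by-phase profiles are out
  of scope.

## A compact worked example

```{r example, eval = FALSE}
# 60 s of a noisy 12-Hz nonsinusoidal oscillation
x <- ar_oscillation(12, r = 0.95, fs = 512, duration_s = 60, seed = 1)
y <- apply_feynman_system(x, K = 1, epsilon = 0.25, noise_sd = 0.2, seed = 2)

# isolate, transform, segment, align
sch <- derive_mask_schedule(y)
trace <- frequency_transform(sch$imfset$imfs[, 3], 512)
cycles <- select_cycles(detect_cycles(trace), list(amp_floor = 0.04, max_if = 18))
profiles <- align_cycles(trace, cycles)

# shape summaries
mean(cycles$p2t_ratio) # < 0.5: widened troughs
if_mean_vector(rowMeans(profiles$profiles))
fit <- fit_shape_pca(profiles, n_comp = 4)
fit
```
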