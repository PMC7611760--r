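# Shared fixture builders. Everything is generated in code; no data files.

# Analytic trace of a pure sinusoid: `n_cycles` cycles of `freq` Hz at `fs`,
# starting at the ascending zero-crossing.
sinusoid_trace <- function(freq = 8, fs = 1000, n_cycles = 8) {
  n <- round(n_cycles * fs / freq)
  x <- sin(2 * pi * freq * (0:(n - 1)) / fs)
  frequency_transform(x, fs)
}

# A long signal made by tiling one schematic cycle, returning its trace.
# Re-analysis of repeated identical cycles gives many good cycles of a known
# shape.
schematic_trace <- function(shape, n_samples = 256, mod_depth = 0.3,
                            n_cycles = 20, fs = n_samples) {
  cyc <- schematic_cycle(shape, n_samples, mod_depth)
  frequency_transform(rep(cyc$waveform, n_cycles), fs)
}

# First good cycle of a trace (start/end bounds), for single-cycle checks.
first_good_cycle <- function(trace) {
  tab <- detect_cycles(trace)
  g <- tab[tab$good, , drop = FALSE]
  stopifnot(nrow(g) >= 1)
  c(g$start[1], g$end[1])
}

# Rank-1 profile set: mean + s_i * v for random scalars s_i (fixed seed).
rank1_profiles <- function(n_cycles = 60, seed = 42, sd_scores = 2) {
  g <- phase_grid(48)
  v <- cos(g) / sqrt(sum(cos(g)^2))
  mu <- rep(10, 48)
  s <- withr::with_seed(seed, stats::rnorm(n_cycles, sd = sd_scores))
  list(
    profiles = outer(v, s) + mu,
    v = v, mu = mu, scores = s
  )
}
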