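#' Data-driven waveform shape motifs by PCA
#'
#' Principal component analysis of the `n_phases x n_cycles` matrix of
#' phase-aligned instantaneous frequency profiles. Each component is a
#' "shape motif": a distribution of IF weights across phase; each cycle's
#' scores say how strongly each motif is expressed in that cycle, and any
#' cycle's shape is approximated by the mean profile plus its score-weighted
#' motifs. Profiles are centered by the mean profile but not variance-scaled
#' per phase bin, preserving the Hz units of the components.
#'
#' @name motifs
NULL

#' Fit shape-motif PCA to phase-aligned profiles
#'
#' Components are the leading eigenvectors of the phase-by-phase covariance
#' across cycles; scores are the projections of the centered profiles. The
#' sign of each component is fixed so that its largest-magnitude loading is
#' positive, making refits deterministic.
#'
#' @param profiles A `cycleshape_profiles` (or bare `n_phases x n_cycles`
#'   matrix).
#' @param n_comp Number of components to retain (default 4).
#' @return A `cycleshape_motifs`: list with `mean_profile`, `components`
#'   (`n_phases x n_comp`, orthonormal columns), `scores`
#'   (`n_comp x n_cycles`), `var_explained` (fraction of total variance per
#'   retained component) and `cycle_ids`.
#' @export
fit_shape_pca <- function(profiles, n_comp = 4L) {
  x <- if (inherits(profiles, "cycleshape_profiles")) profiles$profiles else as.matrix(profiles)
  ids <- if (inherits(profiles, "cycleshape_profiles")) profiles$cycle_ids else seq_len(ncol(x))
  n_cycles <- ncol(x)
  stopifnot(n_comp >= 1L, n_cycles > n_comp)
  mu <- rowMeans(x)
  xc <- x - mu
  cov_pp <- tcrossprod(xc) / (n_cycles - 1L)
  eig <- eigen(cov_pp, symmetric = TRUE)
  rank <- sum(eig$values > max(eig$values) * 1e-12)
  if (n_comp > rank) {
    stop("n_comp (", n_comp, ") exceeds the rank of the profiles (", rank, ")")
  }
  comps <- eig$vectors[, seq_len(n_comp), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(n_comp)) {
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) comps[, j] <- -comps[, j]
  }
  structure(
    list(
      mean_profile = mu,
      components = comps,
      scores = crossprod(comps, xc),
      var_explained = eig$values[seq_len(n_comp)] / sum(eig$values),
      eigenvalues = eig$values,
      cycle_ids = ids
    ),
    class = "cycleshape_motifs"
  )
}

#' @export
print.cycleshape_motifs <- function(x, ...) {
  cat(sprintf(
    "<cycleshape_motifs> %d components over %d cycles; variance explained: %s\n",
    ncol(x$components), ncol(x$scores),
    paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", ")
  ))
  invisible(x)
}

#' Exemplar profiles and waveforms at the extremes of one motif
#'
#' Projects a score vector holding the minimum or maximum observed score
#' for the chosen component (zeros elsewhere) back into profile space, and
#' renders each exemplar as a normalized waveform.
#'
#' @param motifs A `cycleshape_motifs`.
#' @param comp Component index.
#' @param n_out Waveform length (see [normalized_waveform()]).
#' @return A list with `min_profile`, `max_profile`, `min_waveform`,
#'   `max_waveform`.
#' @export
motif_exemplars <- function(motifs, comp = 1L, n_out = 480L) {
  stopifnot(inherits(motifs, "cycleshape_motifs"))
  if (comp < 1L || comp > ncol(motifs$components)) {
    stop("component ", comp, " not fitted")
  }
  sc <- motifs$scores[comp, ]
  mk <- function(score) motifs$mean_profile + score * motifs$components[, comp]
  lo <- mk(min(sc))
  hi <- mk(max(sc))
  if (any(lo <= 0) || any(hi <= 0)) {
    stop("exemplar profile nonpositive; clip the extreme scores before projecting")
  }
  list(
    min_profile = lo, max_profile = hi,
    min_waveform = normalized_waveform(lo, n_out),
    max_waveform = normalized_waveform(hi, n_out)
  )
}

#' Split-half stability of the shape-motif PCA
#'
#' Repeatedly splits the cycles at random into two halves, fits the PCA to
#' each, matches half-components greedily by absolute correlation, and
#' records per-component variance fractions and the absolute correlation
#' between matched component shapes.
#'
#' @param profiles A `cycleshape_profiles` (or matrix).
#' @param n_comp Components per half.
#' @param n_iter Split iterations (default 500).
#' @param seed Integer seed, or `NULL`.
#' @return A list with `var_explained` (`n_iter x n_comp x 2` array) and
#'   `shape_correlations` (`n_iter x n_comp` matrix of matched |r|).
#' @export
split_half_stability <- function(profiles, n_comp = 4L, n_iter = 500L,
                                 seed = NULL) {
  x <- if (inherits(profiles, "cycleshape_profiles")) profiles$profiles else as.matrix(profiles)
  n_cycles <- ncol(x)
  stopifnot(n_cycles >= 2L * (n_comp + 1L), n_iter >= 1L)
  ve <- array(NA_real_, c(n_iter, n_comp, 2L))
  sc <- matrix(NA_real_, n_iter, n_comp)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      half <- sample.int(n_cycles, floor(n_cycles / 2))
      f1 <- fit_shape_pca(x[, half, drop = FALSE], n_comp)
      f2 <- fit_shape_pca(x[, -half, drop = FALSE], n_comp)
      ve[it, , 1L] <- f1$var_explained
      ve[it, , 2L] <- f2$var_explained
      cors <- abs(stats::cor(f1$components, f2$components))
      # greedy matching on |r|
      matched <- numeric(n_comp)
      for (k in seq_len(n_comp)) {
        best <- which(cors == max(cors, na.rm = TRUE), arr.ind = TRUE)[1L, ]
        matched[best[1L]] <- cors[best[1L], best[2L]]
        cors[best[1L], ] <- NA
        cors[, best[2L]] <- NA
      }
      sc[it, ] <- matched
    }
  })
  list(var_explained = ve, shape_correlations = sc)
}
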