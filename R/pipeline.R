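#' End-to-end waveform-shape pipeline
#'
#' Chains the full analysis: input (file or simulation) -> masked sift ->
#' frequency transform of the target IMF -> cycle detection and selection ->
#' phase-aligned profiles -> PCA shape motifs -> (optionally) permutation
#' GLM of motif scores on per-cycle covariates. Every intermediate is
#' written to the output directory together with a JSON run manifest
#' recording parameters, seed and cycle counts at each filtering step.
#'
#' @param config Named list (or path to a JSON file) with fields:
#'   \describe{
#'     \item{input}{path to a time series, or a list
#'       `list(simulate = "ar"|"dynamic", freq_hz, fs, duration_s, ...)`.}
#'     \item{fs}{sampling rate (when not in a sidecar / simulation spec).}
#'     \item{mask_freqs, mask_amps, mask_amp_ratio, n_phases}{mask-sift
#'       schedule; omit `mask_freqs` to derive the zero-crossing halving
#'       schedule from the data.}
#'     \item{imf_index}{which IMF carries the oscillation (default 3).}
#'     \item{criteria}{cycle selection bounds, see [select_cycles()].}
#'     \item{n_bins}{phase grid size (default 48).}
#'     \item{n_comp}{PCA components (default 4).}
#'     \item{covariates}{named list of per-cycle covariate names to model;
#'       must be columns of the cycle table (e.g. `max_ia`,
#'       `duration_samples`) or supplied via `covariate_file`.}
#'     \item{n_perm, alpha}{permutation settings (defaults 5000, 0.01).}
#'     \item{seed}{integer seed.}
#'     \item{out_dir}{output directory (created if needed).}
#'   }
#' @param quiet Suppress per-stage log lines (default `FALSE`; logging goes
#'   to standard error).
#' @return Invisibly, a list with the in-memory artifacts (`imfset`,
#'   `trace`, `cycles`, `included`, `profiles`, `motifs`, `glm`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  log_line <- function(...) if (!quiet) message("[cycleshape] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  ts <- stage("input", {
    if (is.list(config$input) && !is.null(config$input$simulate)) {
      sim <- config$input
      switch(sim$simulate,
        ar = ar_oscillation(sim$freq_hz, sim$r %||% 0.95, sim$fs,
          sim$duration_s,
          seed = seed
        ),
        dynamic = {
          d <- dynamic_shape_signal(sim$freq_hz, sim$fs, sim$duration_s,
            mod_depth = sim$mod_depth %||% 0.3,
            noise_sd = sim$noise_sd, seed = seed
          )
          write_cycles(d$labels, file.path(config$out_dir, "labels.tsv"))
          d$signal
        },
        stop("unknown simulation kind '", sim$simulate, "'")
      )
    } else {
      read_timeseries(config$input, fs = config$fs)
    }
  })
  log_line("input: %d samples @ %g Hz", length(ts$samples), ts$fs)

  imfset <- stage("sift", {
    if (is.null(config$mask_freqs)) {
      derive_mask_schedule(ts, n_phases = config$n_phases %||% 4L)$imfset
    } else {
      sift_masked(ts, config$mask_freqs,
        mask_amp_ratio = config$mask_amp_ratio %||% 2,
        n_phases = config$n_phases %||% 4L,
        mask_amps = config$mask_amps
      )
    }
  })
  write_imfs(imfset, file.path(config$out_dir, "imfs.tsv"))
  log_line("sift: %d IMFs", ncol(imfset$imfs))

  imf_index <- config$imf_index %||% 3L
  trace <- stage("freq", {
    if (imf_index > ncol(imfset$imfs)) {
      stop("imf_index ", imf_index, " but only ", ncol(imfset$imfs), " IMFs")
    }
    frequency_transform(imfset$imfs[, imf_index], imfset$fs)
  })

  cycles_all <- stage("cycles", detect_cycles(trace))
  criteria <- config$criteria %||% list()
  included <- stage("cycles", select_cycles(cycles_all, criteria))
  write_cycles(cycles_all, file.path(config$out_dir, "cycles.tsv"))
  write_cycles(included, file.path(config$out_dir, "cycles_included.tsv"))
  log_line(
    "cycles: %d detected, %d good, %d included",
    nrow(cycles_all), sum(cycles_all$good), nrow(included)
  )

  profiles <- stage("align", align_cycles(trace, included, config$n_bins %||% 48L))
  write_profiles(profiles, file.path(config$out_dir, "profiles.csv"))
  log_line("align: %d profiles on %d-point grid", ncol(profiles$profiles), nrow(profiles$profiles))

  motifs <- stage("motifs", fit_shape_pca(profiles, config$n_comp %||% 4L))
  utils::write.table(
    data.frame(
      phase = profiles$grid, mean_profile = motifs$mean_profile,
      motifs$components
    ),
    file.path(config$out_dir, "motif_components.csv"),
    sep = ",", row.names = FALSE, quote = FALSE
  )
  scores_df <- data.frame(cycle = motifs$cycle_ids, t(motifs$scores))
  names(scores_df)[-1L] <- paste0("PC", seq_len(nrow(motifs$scores)))
  utils::write.table(scores_df, file.path(config$out_dir, "motif_scores.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  log_line(
    "motifs: %d components, %.1f%% variance", ncol(motifs$components),
    100 * sum(motifs$var_explained)
  )

  glm_res <- NULL
  if (!is.null(config$covariates)) {
    glm_res <- stage("glm", {
      covtab <- included
      if (!is.null(config$covariate_file)) {
        extra <- read_covariates(config$covariate_file)
        covtab <- cbind(covtab, extra[match(covtab$cycle, extra$cycle), setdiff(names(extra), "cycle"), drop = FALSE])
      }
      covs <- lapply(stats::setNames(nm = unlist(config$covariates)), function(nm) {
        if (!nm %in% names(covtab)) stop("covariate '", nm, "' not in cycle table")
        covtab[[nm]]
      })
      design <- build_design(covs)
      res <- lapply(seq_len(nrow(motifs$scores)), function(k) {
        permutation_test(design, motifs$scores[k, ],
          n_perm = config$n_perm %||% 5000L,
          alpha = config$alpha %||% 0.01,
          seed = if (is.null(seed)) NULL else seed + k
        )
      })
      rows <- do.call(rbind, lapply(seq_along(res), function(k) {
        r <- res[[k]]
        data.frame(
          outcome = paste0("PC", k),
          regressor = names(r$p_values),
          beta = as.numeric(r$betas[names(r$p_values)]),
          t = as.numeric(r$t_stats[names(r$p_values)]),
          p = as.numeric(r$p_values),
          significant = as.logical(r$significant)
        )
      }))
      utils::write.table(rows, file.path(config$out_dir, "glm.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE
      )
      log_line("glm: %d outcomes x %d regressors", nrow(motifs$scores), ncol(design) - 1L)
      res
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cycleshape")),
    seed = seed,
    fs = ts$fs,
    n_samples = length(ts$samples),
    n_imfs = ncol(imfset$imfs),
    mask_freqs = imfset$mask_freqs,
    mask_amps = imfset$mask_amps,
    imf_index = imf_index,
    n_cycles_detected = nrow(cycles_all),
    n_cycles_good = sum(cycles_all$good),
    n_cycles_included = nrow(included),
    n_bins = config$n_bins %||% 48L,
    n_comp = config$n_comp %||% 4L,
    criteria = criteria
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )

  invisible(list(
    imfset = imfset, trace = trace, cycles = cycles_all, included = included,
    profiles = profiles, motifs = motifs, glm = glm_res, manifest = manifest
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pick the IMF that best carries a target oscillation
#'
#' Returns the index of the IMF whose correlation with a reference signal
#' is highest, or — when no reference is available — the IMF whose
#' amplitude-weighted median instantaneous frequency is nearest a target
#' frequency.
#'
#' @param imfset A `cycleshape_imfs`.
#' @param reference Optional numeric vector (e.g. the noiseless oscillation
#'   in a simulation).
#' @param target_hz Optional target frequency in Hz.
#' @return Integer IMF index.
#' @export
select_imf <- function(imfset, reference = NULL, target_hz = NULL) {
  stopifnot(inherits(imfset, "cycleshape_imfs"))
  if (!is.null(reference)) {
    return(which.max(abs(stats::cor(imfset$imfs, reference))))
  }
  if (is.null(target_hz)) stop("give either `reference` or `target_hz`")
  med_if <- vapply(seq_len(ncol(imfset$imfs)), function(j) {
    tr <- frequency_transform(imfset$imfs[, j], imfset$fs)
    sum(tr$if_hz * tr$ia) / sum(tr$ia)
  }, numeric(1))
  which.min(abs(med_if - target_hz))
}
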