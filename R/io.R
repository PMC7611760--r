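#' Reading and writing pipeline artifacts
#'
#' Time series are accepted as single-column delimited text (TSV/CSV,
#' header optional) with a JSON sidecar giving the sampling rate, or as raw
#' little-endian 64-bit float binary with a mandatory sidecar. All tables
#' are written as plain TSV/CSV with 0-based, half-open sample indexing.
#'
#' @name io
NULL

sidecar_path <- function(path) paste0(path, ".json")

#' Read a single-channel time series
#'
#' @param path Path to a single-column TSV/CSV file or a raw float64
#'   (little-endian) binary file.
#' @param fs Sampling rate in Hz; if `NULL`, read from the JSON sidecar
#'   `<path>.json` (field `fs`), which is mandatory for binary input.
#' @param format `"auto"` (by extension: `.bin`/`.f64`/`.raw` are binary,
#'   anything else text), `"text"` or `"binary"`.
#' @return A `cycleshape_ts`.
#' @export
read_timeseries <- function(path, fs = NULL, format = c("auto", "text", "binary")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bin|f64|raw)$", path)) "binary" else "text"
  }
  if (is.null(fs)) {
    sc <- sidecar_path(path)
    if (!file.exists(sc)) {
      stop("no sampling rate: pass `fs` or provide a sidecar at ", sc)
    }
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(meta$fs)) stop("sidecar ", sc, " lacks an `fs` field")
    fs <- as.numeric(meta$fs)
  }
  samples <- if (format == "binary") {
    n <- file.info(path)$size / 8
    readBin(path, "double", n = n, size = 8, endian = "little")
  } else {
    first <- readLines(path, n = 1L)
    skip <- if (suppressWarnings(is.na(as.numeric(first)))) 1L else 0L
    scan(path, what = double(), skip = skip, quiet = TRUE)
  }
  new_timeseries(samples, fs)
}

#' Write a single-channel time series with its JSON sidecar
#'
#' @param ts A `cycleshape_ts`.
#' @param path Output path; `.bin` writes raw float64, anything else a
#'   single-column TSV. The sidecar `<path>.json` records `fs`, `seed` and
#'   `n_samples`.
#' @param params Optional named list recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, params = NULL) {
  stopifnot(inherits(ts, "cycleshape_ts"))
  if (grepl("\\.(bin|f64|raw)$", path)) {
    writeBin(ts$samples, path, size = 8, endian = "little")
  } else {
    writeLines(format(ts$samples, digits = 17, scientific = FALSE, trim = TRUE), path)
  }
  meta <- list(fs = ts$fs, seed = ts$seed, n_samples = length(ts$samples))
  if (!is.null(params)) meta$params <- params
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write / read an IMF matrix as TSV
#'
#' One column per IMF plus a final `residual` column; the JSON sidecar
#' records the sampling rate and any mask schedule.
#'
#' @param imfset A `cycleshape_imfs`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_imfs <- function(imfset, path) {
  stopifnot(inherits(imfset, "cycleshape_imfs"))
  df <- as.data.frame(imfset$imfs)
  df$residual <- imfset$residual
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fs = imfset$fs, mask_freqs = imfset$mask_freqs, mask_amps = imfset$mask_amps),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_imfs
#' @param fs Sampling rate; if `NULL`, read from the sidecar.
#' @export
read_imfs <- function(path, fs = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  mask_freqs <- NULL
  mask_amps <- NULL
  if (is.null(fs) || file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    if (is.null(fs)) fs <- as.numeric(meta$fs)
    mask_freqs <- meta$mask_freqs
    mask_amps <- meta$mask_amps
  }
  resid <- df$residual
  new_imfset(as.matrix(df[setdiff(names(df), "residual")]), resid, fs,
    mask_freqs = mask_freqs, mask_amps = mask_amps
  )
}

#' Write / read a cycle table as TSV
#' @param table A cycle tibble.
#' @param path Output TSV path.
#' @export
write_cycles <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cycles
#' @export
read_cycles <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE))
}

#' Write / read a phase-profile matrix as CSV
#'
#' First column is the grid phase; remaining columns are one cycle each,
#' named `cycle_<id>`.
#'
#' @param profiles A `cycleshape_profiles`.
#' @param path Output CSV path.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "cycleshape_profiles"))
  df <- data.frame(phase = profiles$grid)
  mat <- as.data.frame(profiles$profiles)
  names(mat) <- paste0("cycle_", profiles$cycle_ids)
  utils::write.table(cbind(df, mat), path,
    sep = ",", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.table(path, sep = ",", header = TRUE)
  ids <- as.integer(sub("^cycle_", "", names(df)[-1L]))
  new_profiles(as.matrix(df[, -1L, drop = FALSE]), cycle_ids = ids)
}

#' Read a per-cycle covariate table (TSV)
#'
#' @param path TSV with a header row; one row per cycle.
#' @return A tibble.
#' @export
read_covariates <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE))
}
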