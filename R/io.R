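#' Read a signal from a two-column time/value CSV
#'
#' Expects a header and two numeric columns `time_s,value`, validates that
#' the time column is strictly increasing and uniformly sampled (within 1%
#' jitter of the median step), and, when `fs_expected` is given, that the
#' sampling rate matches it within 1%.
#'
#' @param path CSV path.
#' @param kind Signal kind, "gsr" or "pulse".
#' @param fs_expected Optional expected sampling rate in Hz.
#' @return An `emg_signal`.
#' @export
load_signal_csv <- function(path, kind = c("gsr", "pulse"),
                            fs_expected = NULL) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  if (ncol(df) != 2L) {
    stop_emg("format_error", "%s: expected 2 columns, found %d",
             path, ncol(df))
  }
  t <- as.numeric(df[[1]])
  v <- as.numeric(df[[2]])
  if (anyNA(t) || anyNA(v)) {
    stop_emg("format_error", "%s: non-numeric entries", path)
  }
  dt <- diff(t)
  bad <- which(dt <= 0)
  if (length(bad) > 0L) {
    stop_emg("format_error",
             "%s: time not strictly increasing at row %d", path, bad[1] + 1L)
  }
  step <- stats::median(dt)
  jit <- which(abs(dt - step) > 0.01 * step)
  if (length(jit) > 0L) {
    stop_emg("format_error",
             "%s: non-uniform sampling at row %d (step %.6g vs %.6g)",
             path, jit[1] + 1L, dt[jit[1]], step)
  }
  fs <- 1 / step
  if (!is.null(fs_expected) && abs(fs - fs_expected) > 0.01 * fs_expected) {
    stop_emg("fs_mismatch", "%s: expected fs=%g Hz, found %g Hz",
             path, fs_expected, fs)
  }
  emg_signal(v, fs = fs, kind = kind, t0 = t[1])
}

#' Write a signal to a two-column CSV
#'
#' @param sig An `emg_signal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(sig, path) {
  stopifnot(inherits(sig, "emg_signal"))
  utils::write.csv(
    data.frame(time_s = signal_times(sig), value = sig$values),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Write a labeled synthetic dataset to a directory
#'
#' One CSV pair per segment plus a `manifest.json` recording labels, seeds
#' and segment duration, so a dataset round-trips through the text formats.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    schema_version = 1L, seed = dataset$seed,
    duration_s = dataset$duration_s,
    segments = lapply(seq_along(dataset$segments), function(i) {
      s <- dataset$segments[[i]]
      gsr_file <- sprintf("segment_%03d_gsr.csv", i)
      pulse_file <- sprintf("segment_%03d_pulse.csv", i)
      write_signal_csv(s$gsr, file.path(dir, gsr_file))
      write_signal_csv(s$pulse, file.path(dir, pulse_file))
      list(id = i, label = s$label, seed = s$seed,
           gsr = gsr_file, pulse = pulse_file)
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return A `synthetic_dataset`.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop_emg("format_error", "no manifest.json in %s", dir)
  manifest <- jsonlite::read_json(mf)
  segs <- lapply(manifest$segments, function(s) {
    list(
      gsr = load_signal_csv(file.path(dir, s$gsr), "gsr"),
      pulse = load_signal_csv(file.path(dir, s$pulse), "pulse"),
      label = s$label, seed = s$seed
    )
  })
  structure(
    list(segments = segs, seed = manifest$seed,
         duration_s = manifest$duration_s),
    class = "synthetic_dataset"
  )
}

#' Default run configuration
#'
#' Nested parameter groups for every pipeline stage, with the package
#' defaults. [validate_config()] rejects unknown keys so typos fail loudly.
#'
#' @return Named list of parameter groups.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    log_level = "info",
    preprocess = list(wavelet = "db4", levels = 5L, cutoff_hz = 10,
                      order = 4L),
    features = list(dead_band = NULL, normalization_scope = "per_segment"),
    calibration = list(variance_keep = 0.85, weight_threshold = 0.6,
                       alpha = 0.05),
    judge = list(smoothing = 1L),
    protocol = list(frame_mode = "wide", inverted = FALSE),
    session = list(window_s = 30, glove_frame_hz = 10,
                   stimulus_duration_s = 30)
  )
}

#' Validate a run configuration against the defaults schema
#'
#' Unknown keys at either level are rejected; known keys override the
#' defaults.
#'
#' @param config Partial configuration list.
#' @return Full configuration with defaults filled in.
#' @export
validate_config <- function(config = list()) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0L) {
    stop_emg("config_error", "unknown config key(s): %s",
             paste(unknown, collapse = ", "))
  }
  for (k in names(config)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      sub_unknown <- setdiff(names(config[[k]]), names(base[[k]]))
      if (length(sub_unknown) > 0L) {
        stop_emg("config_error", "unknown config key(s) under %s: %s",
                 k, paste(sub_unknown, collapse = ", "))
      }
      for (s in names(config[[k]])) base[[k]][[s]] <- config[[k]][[s]]
    } else {
      base[[k]] <- config[[k]]
    }
  }
  base
}
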