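#' Physiological signal container
#'
#' A uniformly sampled physiological trace. `kind` distinguishes the two
#' channels the pipeline knows about: skin-electrical ("gsr", conventionally
#' 20 Hz) and pulse wave ("pulse", conventionally 100 Hz).
#'
#' @param values Numeric vector of samples (arbitrary units). Must be finite
#'   and of length >= 2.
#' @param fs Sampling rate in Hz (> 0).
#' @param kind Signal kind, `"gsr"` or `"pulse"`.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `emg_signal`.
#' @export
#' @examples
#' s <- emg_signal(sin(seq(0, 2 * pi, length.out = 100)), fs = 20, kind = "gsr")
#' signal_duration(s)
emg_signal <- function(values, fs, kind = c("gsr", "pulse"), t0 = 0) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_emg("parameter_error", "`fs` must be a single positive number")
  }
  if (length(values) < 2L) {
    stop_emg("input_too_short", "a signal needs at least 2 samples")
  }
  if (!all(is.finite(values))) {
    stop_emg("parameter_error", "signal values must be finite")
  }
  structure(
    list(values = values, fs = fs, kind = kind, t0 = as.numeric(t0)),
    class = "emg_signal"
  )
}

#' @export
print.emg_signal <- function(x, ...) {
  cat(sprintf(
    "<emg_signal> kind=%s fs=%g Hz n=%d duration=%.2f s t0=%.2f s\n",
    x$kind, x$fs, length(x$values), signal_duration(x), x$t0
  ))
  invisible(x)
}

#' Duration of a signal in seconds
#' @param sig An `emg_signal`.
#' @return Duration in seconds (n / fs).
#' @export
signal_duration <- function(sig) {
  stopifnot(inherits(sig, "emg_signal"))
  length(sig$values) / sig$fs
}

#' Sample times of a signal
#' @param sig An `emg_signal`.
#' @return Numeric vector of per-sample times in seconds.
#' @export
signal_times <- function(sig) {
  stopifnot(inherits(sig, "emg_signal"))
  sig$t0 + (seq_along(sig$values) - 1L) / sig$fs
}

#' Labeled time window of a signal
#'
#' A half-open window `[start_s, end_s)` of a parent signal, optionally
#' carrying an emotion-quadrant label (used by calibration datasets).
#'
#' @param sig An `emg_signal`.
#' @param start_s,end_s Window bounds in seconds relative to `sig$t0`;
#'   `end_s > start_s` and the window must lie within the signal extent.
#' @param label Optional quadrant label (one of [quadrant_levels()]).
#' @return An object of class `emg_segment` whose `$signal` holds the
#'   windowed samples.
#' @export
emg_segment <- function(sig, start_s = 0, end_s = signal_duration(sig),
                        label = NULL) {
  stopifnot(inherits(sig, "emg_signal"))
  if (end_s <= start_s) {
    stop_emg("parameter_error", "segment window must satisfy end_s > start_s")
  }
  dur <- signal_duration(sig)
  if (start_s < 0 || end_s > dur + 1e-9) {
    stop_emg("parameter_error", "segment window outside signal extent")
  }
  if (!is.null(label)) label <- match.arg(label, quadrant_levels())
  i0 <- floor(start_s * sig$fs) + 1L
  i1 <- min(length(sig$values), ceiling(end_s * sig$fs))
  sub <- emg_signal(sig$values[i0:i1], fs = sig$fs, kind = sig$kind,
                    t0 = sig$t0 + (i0 - 1L) / sig$fs)
  structure(
    list(signal = sub, label = label, window = c(start_s, end_s)),
    class = "emg_segment"
  )
}

#' @export
print.emg_segment <- function(x, ...) {
  cat(sprintf(
    "<emg_segment> kind=%s [%.2f, %.2f) s label=%s\n",
    x$signal$kind, x$window[1], x$window[2],
    if (is.null(x$label)) "<none>" else x$label
  ))
  invisible(x)
}

segment_values <- function(seg) {
  stopifnot(inherits(seg, "emg_segment"))
  seg$signal$values
}

# Classed condition constructor shared by all modules: every domain error in
# the package is a condition of class c("emg_<id>", "emg_error", "error").
stop_emg <- function(id, message, ...) {
  cond <- structure(
    class = c(paste0("emg_", id), "emg_error", "error", "condition"),
    list(message = sprintf(message, ...), call = sys.call(-1))
  )
  stop(cond)
}

warn_emg <- function(id, message, ...) {
  cond <- structure(
    class = c(paste0("emg_", id), "emg_warning", "warning", "condition"),
    list(message = sprintf(message, ...), call = sys.call(-1))
  )
  warning(cond)
}
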