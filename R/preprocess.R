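#' Wavelet-denoise a skin-electrical signal
#'
#' Decomposes the trace with a discrete wavelet transform (Daubechies-4,
#' periodized) into approximation and detail bands, soft-thresholds the
#' detail coefficients at the universal threshold, and reconstructs. The
#' slow tonic/phasic structure of skin conductance lives in the
#' approximation bands and passes through; broadband noise is shrunk.
#'
#' @param raw An `emg_signal` of kind "gsr".
#' @param levels Decomposition depth (default 5; capped for short inputs).
#' @return An `emg_signal` of the same length and sampling rate.
#' @export
#' @examples
#' p <- default_presets()$LANV
#' s <- gen_gsr(p, duration_s = 10, seed = 7)
#' d <- denoise_gsr(s)
#' length(d$values) == length(s$values)
denoise_gsr <- function(raw, levels = 5L) {
  stopifnot(inherits(raw, "emg_signal"))
  if (raw$kind != "gsr") {
    stop_emg("type_error", "denoise_gsr expects a signal of kind 'gsr'")
  }
  out <- wavelet_denoise(raw$values, levels = levels)
  sig <- emg_signal(out, fs = raw$fs, kind = "gsr", t0 = raw$t0)
  sig
}

#' Min-max normalize a segment to the 0-100 scale
#'
#' Affine map of the segment values so the minimum becomes 0 and the maximum
#' exactly 100. Order (and hence argmin/argmax) is preserved; the map is
#' idempotent. Constant segments are rejected because range and direction
#' are undefined on them.
#'
#' @param seg An `emg_segment`.
#' @return The segment with normalized values.
#' @export
#' @examples
#' s <- emg_signal(c(1, 3, 2, 5), fs = 20, kind = "gsr")
#' normalize_segment(emg_segment(s))$signal$values  # 0 50 25 100
normalize_segment <- function(seg) {
  stopifnot(inherits(seg, "emg_segment"))
  x <- segment_values(seg)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop_emg("degenerate_input",
             "constant segment: normalization to [0, 100] is undefined")
  }
  seg$signal$values <- (x - rng[1]) / (rng[2] - rng[1]) * 100
  seg
}

#' Zero-phase Butterworth low-pass filter for pulse signals
#'
#' Butterworth low-pass applied forward and backward (filtfilt) so the
#' filter is zero-phase and fiducial-point times are not shifted.
#'
#' @param raw An `emg_signal` of kind "pulse".
#' @param cutoff Cutoff frequency in Hz, 0 < cutoff < fs/2.
#' @param order Filter order (default 4).
#' @return Filtered `emg_signal`, same length and fs.
#' @export
lowpass_pulse <- function(raw, cutoff = 10, order = 4L) {
  stopifnot(inherits(raw, "emg_signal"))
  if (raw$kind != "pulse") {
    stop_emg("type_error", "lowpass_pulse expects a signal of kind 'pulse'")
  }
  if (cutoff <= 0 || cutoff >= raw$fs / 2) {
    stop_emg("parameter_error",
             "cutoff must lie strictly between 0 and Nyquist (%g Hz)",
             raw$fs / 2)
  }
  bf <- signal::butter(order, cutoff / (raw$fs / 2), type = "low")
  # odd-reflection padding so the forward-backward filter's startup
  # transients decay inside the pad, preserving DC and edge fidelity
  x <- raw$values
  n <- length(x)
  pad <- min(n - 1L, max(24L, ceiling(3 * raw$fs / cutoff) * order))
  pre <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(pre, x, post))[(pad + 1L):(pad + n)]
  emg_signal(y, fs = raw$fs, kind = "pulse", t0 = raw$t0)
}

#' Cut a signal into fixed-length windows
#'
#' Half-open windows `[k * hop_s, k * hop_s + window_s)`; a final window that
#' would overrun the signal end is dropped.
#'
#' @param sig An `emg_signal`.
#' @param window_s Window length in seconds (<= signal duration).
#' @param hop_s Hop between window starts in seconds (> 0); defaults to
#'   `window_s` (non-overlapping).
#' @return List of `emg_segment`s.
#' @export
segment_stream <- function(sig, window_s, hop_s = window_s) {
  stopifnot(inherits(sig, "emg_signal"))
  if (hop_s <= 0) stop_emg("parameter_error", "hop_s must be positive")
  dur <- signal_duration(sig)
  if (window_s > dur) {
    stop_emg("parameter_error",
             "window_s (%g s) exceeds signal duration (%g s)", window_s, dur)
  }
  starts <- seq(0, dur - window_s + 1e-9, by = hop_s)
  starts <- starts[starts + window_s <= dur + 1e-9]
  lapply(starts, function(s0) emg_segment(sig, s0, s0 + window_s))
}
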