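#' Detect beats in a pulse-wave signal
#'
#' Locates one systolic peak per beat using a prominence/height rule with a
#' physiological refractory period: peaks must exceed 55% of the signal's
#' amplitude range and be at least `refractory_ms` apart. Onsets are taken
#' as the minimum between consecutive peaks (and the pre-peak minimum for
#' the first beat). Intervals are successive peak-to-peak times in ms;
#' peak-to-peak is used because pulse-wave onsets are less stable under
#' noise than the systolic maximum.
#'
#' @param pulse A filtered `emg_signal` of kind "pulse" containing at least
#'   two beats.
#' @param refractory_ms Minimum peak-to-peak spacing in ms (default 300).
#' @param min_height_frac Peak height threshold as a fraction of the
#'   amplitude range above the minimum (default 0.55, between the dicrotic
#'   wave at ~40% and the systolic peak).
#' @return A `beat_series`: list with `onsets` (s), `peaks` (s),
#'   `intervals` (ms).
#' @export
detect_beats <- function(pulse, refractory_ms = 300, min_height_frac = 0.55) {
  stopifnot(inherits(pulse, "emg_signal"))
  if (pulse$kind != "pulse") {
    stop_emg("type_error", "detect_beats expects a signal of kind 'pulse'")
  }
  x <- pulse$values
  rng <- range(x)
  if (rng[2] - rng[1] < .Machine$double.eps^0.5) {
    stop_emg("insufficient_data", "constant signal: no beats present")
  }
  thr <- rng[1] + min_height_frac * (rng[2] - rng[1])
  mind <- max(1L, round(refractory_ms / 1000 * pulse$fs))
  pk <- pracma::findpeaks(x, minpeakheight = thr, minpeakdistance = mind)
  if (is.null(pk) || nrow(pk) < 2L) {
    stop_emg("insufficient_data", "fewer than 2 beats detected")
  }
  pidx <- sort(pk[, 2])
  onsets_idx <- integer(length(pidx))
  # first onset: minimum over the pre-peak span of one refractory period
  lo <- max(1L, pidx[1] - 2L * mind)
  onsets_idx[1] <- lo + which.min(x[lo:pidx[1]]) - 1L
  for (k in seq_len(length(pidx) - 1L)) {
    span <- pidx[k]:pidx[k + 1L]
    onsets_idx[k + 1L] <- span[which.min(x[span])]
  }
  t0 <- pulse$t0
  structure(
    list(
      onsets = t0 + (onsets_idx - 1L) / pulse$fs,
      peaks = t0 + (pidx - 1L) / pulse$fs,
      peak_idx = pidx,
      onset_idx = onsets_idx,
      intervals = diff(pidx) / pulse$fs * 1000
    ),
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, mean interval %.0f ms\n",
              length(x$peaks), mean(x$intervals)))
  invisible(x)
}

#' Locate pulse-wave fiducial points within one beat
#'
#' Within one inter-onset span containing a single systolic peak, locates
#' the classic pulse-wave landmarks: b1 (onset minimum / aortic valve
#' opening), c (systolic peak), e (dicrotic notch, the lowest local minimum
#' after c), g (dicrotic-wave peak, the highest local maximum after e), and
#' the shoulder points d (on the falling limb between c and e) and f
#' (between e and g), found as extrema of the first derivative. Amplitudes
#' h1-h4 are measured above the b1 baseline; times t1 (onset to c), t2
#' (onset to e) and t (span duration) in seconds.
#'
#' A beat with no post-peak local minimum (no dicrotic notch) is returned
#' with `degenerate = TRUE` and e/f/g, h3/h4 and t2 missing.
#'
#' @param pulse An `emg_signal` of kind "pulse".
#' @param span Integer indices (into the signal) of one inter-onset span.
#' @return A `fiducial_set` list: indices `b1,c,d,e,f,g` (relative to the
#'   signal), amplitudes `h1..h4`, times `t1,t2,t`, flag `degenerate`.
#' @export
locate_fiducials <- function(pulse, span) {
  stopifnot(inherits(pulse, "emg_signal"))
  span <- as.integer(span)
  x <- pulse$values[span]
  n <- length(x)
  if (n < 5L) stop_emg("insufficient_data", "beat span too short")
  fs <- pulse$fs
  b1 <- 1L
  cpk <- which.max(x)
  if (cpk <= b1) b1 <- which.min(x[1:cpk])
  base <- x[b1]
  # local minima strictly after the systolic peak
  interior <- if (cpk + 1L <= n - 1L) (cpk + 1L):(n - 1L) else integer(0)
  is_lmin <- interior[x[interior] <= x[interior - 1L] &
                      x[interior] <= x[interior + 1L]]
  if (length(is_lmin) == 0L) {
    return(structure(list(
      b1 = span[b1], c = span[cpk], d = NA_integer_, e = NA_integer_,
      f = NA_integer_, g = NA_integer_,
      h1 = x[cpk] - base, h2 = NA_real_, h3 = NA_real_, h4 = NA_real_,
      t1 = (cpk - b1) / fs, t2 = NA_real_, t = n / fs,
      degenerate = TRUE
    ), class = "fiducial_set"))
  }
  e <- is_lmin[which.min(x[is_lmin])]
  # dicrotic peak: highest local maximum after the notch (fall back to the
  # global maximum after e when the tail is monotone)
  after <- if (e + 1L <= n - 1L) (e + 1L):(n - 1L) else integer(0)
  lmax <- after[x[after] >= x[after - 1L] & x[after] >= x[after + 1L]]
  g <- if (length(lmax) > 0L) lmax[which.max(x[lmax])] else
    (e:n)[which.max(x[e:n])]
  dx <- diff(x)
  # d: least-steep point (max of derivative) on the falling limb (c, e);
  # f: steepest rise (max of derivative) on the pre-dicrotic limb (e, g)
  d_rng <- if (e - cpk >= 2L) (cpk + 1L):(e - 1L) else integer(0)
  d <- if (length(d_rng) > 0L) d_rng[which.max(dx[d_rng - 1L])] else
    as.integer(floor((cpk + e) / 2))
  f_rng <- if (g - e >= 2L) (e + 1L):(g - 1L) else integer(0)
  f <- if (length(f_rng) > 0L) f_rng[which.max(dx[f_rng])] else
    as.integer(ceiling((e + g) / 2))
  d <- max(min(d, e - 1L), cpk + 1L)
  f <- max(min(f, g), e + 1L)
  structure(list(
    b1 = span[b1], c = span[cpk], d = span[d], e = span[e],
    f = span[f], g = span[g],
    h1 = x[cpk] - base, h2 = x[d] - base, h3 = x[e] - base,
    h4 = x[g] - base,
    t1 = (cpk - b1) / fs, t2 = (e - b1) / fs, t = n / fs,
    degenerate = FALSE
  ), class = "fiducial_set")
}

#' Fiducial table for all beats of a signal
#'
#' Convenience wrapper running [locate_fiducials()] on every inter-onset
#' span of a [detect_beats()] result.
#'
#' @param pulse An `emg_signal` of kind "pulse".
#' @param beats A `beat_series` from [detect_beats()].
#' @return Data frame with one row per beat:
#'   `beat_idx,b1,c,d,e,f,g,h1,h2,h3,h4,t1,t2,t,degenerate`.
#' @export
fiducial_table <- function(pulse, beats) {
  stopifnot(inherits(beats, "beat_series"))
  oi <- beats$onset_idx
  rows <- lapply(seq_len(length(oi) - 1L), function(k) {
    fs <- locate_fiducials(pulse, oi[k]:(oi[k + 1L] - 1L))
    data.frame(beat_idx = k, b1 = fs$b1, c = fs$c, d = fs$d, e = fs$e,
               f = fs$f, g = fs$g, h1 = fs$h1, h2 = fs$h2, h3 = fs$h3,
               h4 = fs$h4, t1 = fs$t1, t2 = fs$t2, t = fs$t,
               degenerate = fs$degenerate)
  })
  do.call(rbind, rows)
}

#' BpNN50: percentage of successive beat-interval differences above 50 ms
#'
#' The pNN50-style heart-rate-variability statistic on the pulse-wave beat
#' intervals: 100 times the fraction of successive interval differences
#' whose absolute value strictly exceeds 50 ms.
#'
#' @param beats A `beat_series`, or a numeric vector of intervals in ms.
#' @param threshold_ms Difference threshold in ms (default 50).
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' bpnn50(c(800, 860, 855, 900))  # diffs 60, 5, 45 -> 33.33
bpnn50 <- function(beats, threshold_ms = 50) {
  ivl <- if (inherits(beats, "beat_series")) beats$intervals else
    as.numeric(beats)
  if (length(ivl) < 2L) {
    stop_emg("insufficient_data", "need at least 2 intervals for BpNN50")
  }
  d <- abs(diff(ivl))
  100 * mean(d > threshold_ms)
}
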