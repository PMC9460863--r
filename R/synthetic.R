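#' Quadrant preset for the synthetic generators
#'
#' Parameterizes how one valence-arousal quadrant expresses itself in the
#' synthetic signals: phasic skin-conductance activity (`scr_rate`,
#' `scr_amp`), the signed tonic drift (`trend_slope`), beat-interval
#' variability (`hrv_pnn50_target`) and mean heart rate.
#'
#' @param label Quadrant code, one of [quadrant_levels()].
#' @param scr_rate Phasic skin-conductance responses per minute (>= 0).
#' @param scr_amp Mean phasic response amplitude, arbitrary units (>= 0).
#' @param trend_slope Signed tonic drift in a.u. per second.
#' @param hrv_pnn50_target Target fraction of successive beat-interval
#'   differences exceeding 50 ms, in \[0, 1\].
#' @param mean_hr Mean heart rate in beats per minute, in \[30, 200\].
#' @param noise_sd Standard deviation of additive Gaussian measurement noise
#'   on the skin-electrical trace (a.u.).
#' @return A `quadrant_preset` list.
#' @export
quadrant_preset <- function(label, scr_rate, scr_amp, trend_slope,
                            hrv_pnn50_target, mean_hr, noise_sd = 0.05) {
  label <- match.arg(label, quadrant_levels())
  if (scr_rate < 0 || scr_amp < 0) {
    stop_emg("parameter_error", "scr_rate and scr_amp must be non-negative")
  }
  if (hrv_pnn50_target < 0 || hrv_pnn50_target > 1) {
    stop_emg("parameter_error", "hrv_pnn50_target must lie in [0, 1]")
  }
  if (mean_hr < 30 || mean_hr > 200) {
    stop_emg("parameter_error", "mean_hr must lie in [30, 200] bpm")
  }
  structure(
    list(label = label, scr_rate = scr_rate, scr_amp = scr_amp,
         trend_slope = trend_slope, hrv_pnn50_target = hrv_pnn50_target,
         mean_hr = mean_hr, noise_sd = noise_sd),
    class = "quadrant_preset"
  )
}

#' Default quadrant presets
#'
#' One preset per quadrant, encoding the pipeline's own working assumptions
#' rather than physiological ground truth: high-arousal quadrants show dense,
#' large phasic activity (large skin-electrical range) and a rising tonic
#' trend; low-arousal quadrants sparse small activity and a mildly falling
#' trend; positive valence shows high beat-interval variability (BpNN50),
#' negative valence low. This closes the loop for parameter-recovery tests.
#'
#' @param separation Scale in (0, 1] shrinking every preset toward the
#'   across-preset mean; 1 keeps the defaults, smaller values make the
#'   quadrants harder to distinguish.
#' @return Named list of four `quadrant_preset`s (HAPV, HANV, LANV, LAPV).
#' @export
default_presets <- function(separation = 1) {
  if (separation <= 0 || separation > 1) {
    stop_emg("parameter_error", "separation must lie in (0, 1]")
  }
  p <- list(
    HAPV = quadrant_preset("HAPV", scr_rate = 10, scr_amp = 1.0,
                           trend_slope = 0.06, hrv_pnn50_target = 0.60,
                           mean_hr = 90),
    HANV = quadrant_preset("HANV", scr_rate = 10, scr_amp = 1.0,
                           trend_slope = 0.06, hrv_pnn50_target = 0.10,
                           mean_hr = 95),
    LANV = quadrant_preset("LANV", scr_rate = 2, scr_amp = 0.3,
                           trend_slope = -0.02, hrv_pnn50_target = 0.15,
                           mean_hr = 70),
    LAPV = quadrant_preset("LAPV", scr_rate = 2, scr_amp = 0.3,
                           trend_slope = -0.02, hrv_pnn50_target = 0.65,
                           mean_hr = 65)
  )
  if (separation < 1) {
    num <- c("scr_rate", "scr_amp", "trend_slope", "hrv_pnn50_target",
             "mean_hr")
    for (f in num) {
      m <- mean(vapply(p, `[[`, numeric(1), f))
      for (q in names(p)) p[[q]][[f]] <- m + separation * (p[[q]][[f]] - m)
    }
  }
  p
}

#' Generate a synthetic skin-electrical (GSR) trace
#'
#' Tonic baseline plus signed linear drift plus a train of phasic
#' skin-conductance responses (bi-exponential rise/decay, rise tau 0.75 s,
#' decay tau 2 s) at Poisson event times, plus Gaussian noise. Deterministic
#' for a fixed seed.
#'
#' @param preset A [quadrant_preset()].
#' @param duration_s Trace duration in seconds (> 0).
#' @param fs Sampling rate in Hz; the glove samples skin conductance at 20 Hz.
#' @param seed Integer seed.
#' @param baseline Tonic level in a.u.
#' @return An `emg_signal` of kind "gsr". The Poisson event times are
#'   attached as attribute `"scr_times"`.
#' @export
gen_gsr <- function(preset, duration_s = 30, fs = 20, seed = 1,
                    baseline = 5) {
  stopifnot(inherits(preset, "quadrant_preset"))
  if (duration_s <= 0 || fs <= 0) {
    stop_emg("parameter_error", "duration_s and fs must be positive")
  }
  # grid spans [0, duration_s] inclusive, so a pure linear trend rises by
  # exactly trend_slope * duration_s over the trace
  n <- round(duration_s * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  # closed-form peak of the bi-exponential kernel (rise 0.75 s, decay 2 s),
  # so event amplitudes are in output units
  t_pk <- log(2 / 0.75) / (1 / 0.75 - 1 / 2)
  pk <- exp(-t_pk / 2.0) - exp(-t_pk / 0.75)
  with_seed(derive_seed(seed, "gsr"), {
    x <- baseline + preset$trend_slope * t
    n_ev <- stats::rpois(1L, preset$scr_rate * duration_s / 60)
    ev_t <- sort(stats::runif(n_ev, 0, duration_s))
    ev_a <- if (n_ev > 0) {
      preset$scr_amp * stats::rlnorm(n_ev, meanlog = -0.045, sdlog = 0.3)
    } else {
      numeric(0)
    }
    for (k in seq_len(n_ev)) {
      dt <- t - ev_t[k]
      on <- dt >= 0
      shape <- exp(-dt[on] / 2.0) - exp(-dt[on] / 0.75)
      x[on] <- x[on] + ev_a[k] * shape / pk
    }
    if (preset$noise_sd > 0) x <- x + stats::rnorm(n, sd = preset$noise_sd)
    out <- emg_signal(x, fs = fs, kind = "gsr")
    attr(out, "scr_times") <- ev_t
    out
  })
}

# Beat-interval sequence whose successive differences exceed 50 ms with
# probability ~ target: a bounded random walk that jumps 65 ms on a "large"
# step and 15 ms otherwise (65 ms leaves margin for the 10 ms sampling
# quantization of a 100 Hz trace; 15 ms stays below 50 ms even after it).
gen_beat_intervals <- function(n_beats, mean_hr, pnn50_target) {
  base <- 60 / mean_hr                      # seconds
  e <- numeric(n_beats)
  for (k in 2:n_beats) {
    big <- stats::runif(1) < pnn50_target
    step <- if (big) 0.065 else 0.015
    s <- sample(c(-1, 1), 1L)
    if (abs(e[k - 1L] + s * step) > 0.100) s <- -s
    e[k] <- e[k - 1L] + s * step
  }
  pmax(base + e, 0.3)
}

#' Generate a synthetic pulse-wave (PPG) trace
#'
#' Each beat is the sum of two Gaussian bumps: the dominant systolic wave and
#' a smaller, delayed dicrotic wave (40% amplitude at 35% of the beat
#' interval after the systolic peak), producing a dicrotic notch between
#' them. Beat-to-beat intervals are drawn so the fraction of successive
#' interval differences above 50 ms approximates `hrv_pnn50_target`.
#'
#' @inheritParams gen_gsr
#' @param fs Sampling rate in Hz; must be >= 50 so the notch is resolvable.
#'   The glove pulse sensor samples at 100 Hz.
#' @param amp Systolic amplitude in a.u.
#' @param noise_sd Additive Gaussian noise (a.u.).
#' @return An `emg_signal` of kind "pulse" with attributes `"beat_times"`
#'   (ground-truth systolic peak times, s) and `"intervals_ms"`.
#' @export
gen_ppg <- function(preset, duration_s = 30, fs = 100, seed = 1,
                    amp = 1, noise_sd = 0.01) {
  stopifnot(inherits(preset, "quadrant_preset"))
  if (fs < 50) {
    stop_emg("parameter_error",
             "fs must be >= 50 Hz to resolve the dicrotic notch")
  }
  if (duration_s <= 0) stop_emg("parameter_error", "duration_s must be positive")
  with_seed(derive_seed(seed, "ppg"), {
    n_max <- ceiling(duration_s * preset$mean_hr / 60) + 10L
    ivl <- gen_beat_intervals(n_max, preset$mean_hr, preset$hrv_pnn50_target)
    onset <- cumsum(c(0.1, ivl))
    keep <- onset < duration_s
    onset <- onset[keep]
    n <- round(duration_s * fs) + 1L
    t <- (seq_len(n) - 1L) / fs
    x <- numeric(n)
    peak_t <- numeric(length(onset))
    base <- 60 / preset$mean_hr
    for (k in seq_along(onset)) {
      T_k <- if (k < length(onset)) onset[k + 1L] - onset[k] else
        ivl[min(k, length(ivl))]
      # fixed systolic offset after onset, so peak-to-peak intervals equal
      # the generated onset intervals exactly
      ts <- onset[k] + 0.18 * base
      td <- ts + 0.35 * T_k                    # dicrotic center
      s1 <- 0.06 * T_k
      s2 <- 0.09 * T_k
      win <- t >= onset[k] - 0.05 & t <= onset[k] + 1.6 * T_k
      x[win] <- x[win] + amp * exp(-(t[win] - ts)^2 / (2 * s1^2)) +
        0.4 * amp * exp(-(t[win] - td)^2 / (2 * s2^2))
      peak_t[k] <- ts
    }
    if (noise_sd > 0) x <- x + stats::rnorm(n, sd = noise_sd)
    out <- emg_signal(x, fs = fs, kind = "pulse")
    keep_pk <- peak_t < duration_s - 0.05
    attr(out, "beat_times") <- peak_t[keep_pk]
    attr(out, "intervals_ms") <- diff(peak_t[keep_pk]) * 1000
    out
  })
}

#' Generate a balanced labeled calibration dataset
#'
#' @param presets Named list of four [quadrant_preset()]s, one per quadrant.
#' @param n_per_class Segments per quadrant (>= 1).
#' @param seed Integer seed; each segment gets an independent derived seed.
#' @param duration_s Segment duration in seconds (the stimulus length; the
#'   music pieces driving the original system last about 30 s).
#' @return A `synthetic_dataset`: list with `segments` (each holding `gsr`,
#'   `pulse`, `label`, `seed`), `seed` and `duration_s`.
#' @export
gen_labeled_dataset <- function(presets = default_presets(), n_per_class = 10,
                                seed = 1, duration_s = 30) {
  labels <- vapply(presets, `[[`, character(1), "label")
  if (length(presets) != 4L || anyDuplicated(labels) ||
      !setequal(labels, quadrant_levels())) {
    stop_emg("parameter_error",
             "presets must contain exactly one preset per quadrant")
  }
  if (n_per_class < 1) stop_emg("parameter_error", "n_per_class must be >= 1")
  segs <- list()
  idx <- 0L
  for (q in quadrant_levels()) {
    p <- presets[[which(labels == q)]]
    for (r in seq_len(n_per_class)) {
      idx <- idx + 1L
      seg_seed <- derive_seed(seed, sprintf("segment-%s-%d", q, r))
      segs[[idx]] <- list(
        gsr = gen_gsr(p, duration_s = duration_s, seed = seg_seed),
        pulse = gen_ppg(p, duration_s = duration_s, seed = seg_seed),
        label = q, seed = seg_seed
      )
    }
  }
  structure(
    list(segments = segs, seed = seed, duration_s = duration_s),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  labs <- vapply(x$segments, `[[`, character(1), "label")
  cat(sprintf("<synthetic_dataset> %d segments x %g s (seed %s)\n",
              length(x$segments), x$duration_s, format(x$seed)))
  print(table(labs))
  invisible(x)
}

#' Generate block-structured session signals
#'
#' Concatenates one fixed-length stimulus block per requested quadrant, in
#' order, producing a continuous skin-electrical trace and pulse trace for
#' an end-to-end control-session simulation. Each block is trimmed to
#' exactly `block_s` seconds so block boundaries align with judgment
#' windows.
#'
#' @param presets Named list of presets (as [default_presets()]).
#' @param order Character vector of quadrant codes, one per stimulus block.
#' @param seed Integer seed.
#' @param block_s Block length in seconds (default 30, the stimulus
#'   duration).
#' @return List with `gsr` and `pulse` (`emg_signal`s) and `labels`
#'   (= `order`).
#' @export
gen_session_signals <- function(presets = default_presets(),
                                order = c("HANV", "LANV", "HAPV", "LAPV"),
                                seed = 1, block_s = 30) {
  labels <- vapply(presets, `[[`, character(1), "label")
  g_all <- numeric(0)
  p_all <- numeric(0)
  for (k in seq_along(order)) {
    p <- presets[[which(labels == order[k])]]
    s <- derive_seed(seed, sprintf("session-block-%d", k))
    g <- gen_gsr(p, duration_s = block_s, seed = s)
    pw <- gen_ppg(p, duration_s = block_s, seed = s)
    g_all <- c(g_all, g$values[seq_len(block_s * g$fs)])
    p_all <- c(p_all, pw$values[seq_len(block_s * pw$fs)])
  }
  list(
    gsr = emg_signal(g_all, fs = 20, kind = "gsr"),
    pulse = emg_signal(p_all, fs = 100, kind = "pulse"),
    labels = order
  )
}

#' Generate a synthetic glove byte stream
#'
#' Encodes the given finger-bend tuples and IMU orientation angles into the
#' glove wire format (finger frames interleaved with angle packets) so that
#' decoding recovers the inputs within quantization error.
#'
#' @param finger_bends Matrix (or 5-column data frame) of bend angles in
#'   degrees, thumb to little finger, each in \[0, 180\].
#' @param imu_angles Matrix with columns roll/pitch/yaw in degrees, each in
#'   \[-180, 180\].
#' @param seed Integer seed (reserved for future jitter models; the encoding
#'   itself is deterministic).
#' @param model A [sensor_model()].
#' @return A raw vector: interleaved finger frames and angle packets.
#' @export
gen_glove_stream <- function(finger_bends = NULL, imu_angles = NULL, seed = 1,
                             model = sensor_model()) {
  fb <- if (is.null(finger_bends)) matrix(numeric(0), ncol = 5) else
    as.matrix(finger_bends)
  im <- if (is.null(imu_angles)) matrix(numeric(0), ncol = 3) else
    as.matrix(imu_angles)
  if (ncol(fb) != 5L) stop_emg("parameter_error", "finger_bends needs 5 columns")
  if (ncol(im) != 3L) stop_emg("parameter_error", "imu_angles needs 3 columns")
  if (nrow(fb) > 0 && (min(fb) < 0 || max(fb) > 180)) {
    stop_emg("parameter_error", "bend angles must lie in [0, 180] degrees")
  }
  if (nrow(im) > 0 && (min(im) < -180 || max(im) > 180)) {
    stop_emg("parameter_error", "IMU angles must lie in [-180, 180] degrees")
  }
  out <- raw(0)
  n <- max(nrow(fb), nrow(im))
  for (k in seq_len(n)) {
    if (k <= nrow(fb)) {
      counts <- vapply(fb[k, ], function(deg) {
        adc_from_resistance(resistance_from_bend(deg, model), model)
      }, numeric(1))
      out <- c(out, encode_finger_frame(counts, model = model))
    }
    if (k <= nrow(im)) {
      out <- c(out, encode_imu_frame("angle", im[k, ]))
    }
  }
  out
}
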