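#' Map an emotion quadrant to an animation gesture
#'
#' Fixed bijection driving the virtual hand: gestures "1", "2", "3", "4"
#' correspond to HANV, LANV, HAPV, LAPV respectively.
#'
#' @param label An [emotion_label()] or quadrant code.
#' @param t Event time in seconds.
#' @return A `gesture_command`: `gesture_id`, `source = "emotion"`, `t`.
#' @export
#' @examples
#' map_emotion_to_gesture("HANV")$gesture_id  # "1"
map_emotion_to_gesture <- function(label, t = NA_real_) {
  q <- if (inherits(label, "emotion_label")) label$quadrant else
    emotion_label(label)$quadrant
  gid <- c(HANV = "1", LANV = "2", HAPV = "3", LAPV = "4")[[q]]
  structure(list(gesture_id = gid, source = "emotion", t = t),
            class = "gesture_command")
}

#' Map an emotion quadrant to a steering direction
#'
#' Fixed bijection driving the manipulator: up (HANV), left (LANV),
#' right (HAPV), down (LAPV).
#'
#' @inheritParams map_emotion_to_gesture
#' @return A `steering_command`: `direction`, `t`.
#' @export
#' @examples
#' map_emotion_to_steering("HAPV")$direction  # "right"
map_emotion_to_steering <- function(label, t = NA_real_) {
  q <- if (inherits(label, "emotion_label")) label$quadrant else
    emotion_label(label)$quadrant
  dir <- c(HANV = "up", LANV = "left", HAPV = "right", LAPV = "down")[[q]]
  structure(list(direction = dir, t = t), class = "steering_command")
}

#' Timing deviation between two gesture-event streams
#'
#' Matches events greedily in order by `gesture_id` (each virtual event
#' takes the earliest unmatched manipulator event with the same gesture)
#' and reports the signed deviation
#' `100 * (t_manipulator - t_virtual) / stimulus_duration_s` per matched
#' pair. Unmatched events get a missing deviation (the "X" cells of a
#' deviation table).
#'
#' @param virtual_events,manipulator_events Data frames (or lists of
#'   `gesture_command`s) with columns/fields `gesture_id` and `t`.
#' @param stimulus_duration_s Denominator of the percentage; the stimulus
#'   length (default 30 s, the nominal music-piece duration).
#' @return Data frame with `gesture_id`, `t_virtual`, `t_manipulator`,
#'   `deviation_pct` (NA when unmatched), `matched`.
#' @export
timing_deviation <- function(virtual_events, manipulator_events,
                             stimulus_duration_s = 30) {
  if (stimulus_duration_s <= 0) {
    stop_emg("parameter_error", "stimulus_duration_s must be positive")
  }
  ve <- as_event_df(virtual_events)
  me <- as_event_df(manipulator_events)
  if (nrow(ve) == 0L && nrow(me) == 0L) {
    return(data.frame(gesture_id = character(0), t_virtual = numeric(0),
                      t_manipulator = numeric(0), deviation_pct = numeric(0),
                      matched = logical(0)))
  }
  used <- rep(FALSE, nrow(me))
  rows <- lapply(seq_len(nrow(ve)), function(i) {
    cand <- which(!used & me$gesture_id == ve$gesture_id[i])
    if (length(cand) > 0L) {
      j <- cand[which.min(me$t[cand])]
      used[j] <<- TRUE
      data.frame(gesture_id = ve$gesture_id[i], t_virtual = ve$t[i],
                 t_manipulator = me$t[j],
                 deviation_pct = 100 * (me$t[j] - ve$t[i]) /
                   stimulus_duration_s,
                 matched = TRUE)
    } else {
      data.frame(gesture_id = ve$gesture_id[i], t_virtual = ve$t[i],
                 t_manipulator = NA_real_, deviation_pct = NA_real_,
                 matched = FALSE)
    }
  })
  extra <- which(!used)
  rows <- c(rows, lapply(extra, function(j) {
    data.frame(gesture_id = me$gesture_id[j], t_virtual = NA_real_,
               t_manipulator = me$t[j], deviation_pct = NA_real_,
               matched = FALSE)
  }))
  do.call(rbind, rows)
}

as_event_df <- function(ev) {
  if (is.data.frame(ev)) {
    return(data.frame(gesture_id = as.character(ev$gesture_id),
                      t = as.numeric(ev$t)))
  }
  if (length(ev) == 0L) {
    return(data.frame(gesture_id = character(0), t = numeric(0)))
  }
  data.frame(
    gesture_id = vapply(ev, `[[`, character(1), "gesture_id"),
    t = vapply(ev, `[[`, numeric(1), "t")
  )
}

#' Classify a gesture id from finger-bend angles
#'
#' The counting gestures "1".."4" extend that many non-thumb fingers:
#' a finger is extended when its bend is at most `extended_deg`, curled
#' when at least `curled_deg`. Hands that match no counting gesture give
#' NA.
#'
#' @param angles_deg Length-5 bends in degrees (thumb first).
#' @param extended_deg,curled_deg Classification thresholds.
#' @return "1".."4" or NA.
#' @export
gesture_from_bends <- function(angles_deg, extended_deg = 45,
                               curled_deg = 100) {
  stopifnot(length(angles_deg) == 5L)
  fingers <- angles_deg[2:5]
  n_ext <- sum(fingers <= extended_deg)
  n_curl <- sum(fingers >= curled_deg)
  if (n_ext >= 1L && n_ext <= 4L && n_ext + n_curl == 4L) {
    as.character(n_ext)
  } else {
    NA_character_
  }
}

#' Run a simulated dual-channel control session
#'
#' Windows the physiological signals, runs the per-window pipeline
#' (denoise, low-pass, beat detection, feature extraction, quadrant
#' judgment) and emits an emotion-driven gesture event at the end of each
#' judged window on the `virtual_hand` channel. In parallel, decodes the
#' glove byte stream into finger frames, classifies counting gestures and
#' emits an event on the `manipulator` channel whenever the gesture
#' changes. Window-level pipeline errors are logged and the session
#' continues.
#'
#' @param gsr `emg_signal` of kind "gsr".
#' @param pulse `emg_signal` of kind "pulse", same time span.
#' @param glove_stream Raw vector (possibly empty) of glove frames.
#' @param model A `calibration_model`.
#' @param window_s Judgment window in seconds (default 30, the stimulus
#'   length).
#' @param glove_frame_hz Rate at which glove frames were sampled, used to
#'   assign frame timestamps (default 10 Hz).
#' @param sensor A [sensor_model()].
#' @return A `session_report`: `events` data frame (`t`, `channel`,
#'   `gesture_id`, `quadrant`), `deviations` (from [timing_deviation()]),
#'   `summary` (counts, fraction of matched pairs with |deviation| < 20%),
#'   `errors` (per-window error messages).
#' @export
run_session <- function(gsr, pulse, glove_stream = raw(0), model,
                        window_s = 30, glove_frame_hz = 10,
                        sensor = sensor_model()) {
  stopifnot(inherits(model, "calibration_model"))
  g_segs <- segment_stream(gsr, window_s)
  errors <- character(0)
  v_events <- list()
  for (k in seq_along(g_segs)) {
    res <- tryCatch({
      w <- g_segs[[k]]$window
      gd <- denoise_gsr(g_segs[[k]]$signal)
      pseg <- emg_segment(pulse, w[1], min(w[2], signal_duration(pulse)))
      pf <- lowpass_pulse(pseg$signal)
      fv <- extract_features(emg_segment(gd), detect_beats(pf))
      lab <- judge_segment(fv, model)$label
      map_emotion_to_gesture(lab, t = w[2])
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors <- c(errors, sprintf("window %d: %s", k, res))
    } else {
      v_events[[length(v_events) + 1L]] <- res
    }
  }
  m_events <- list()
  if (length(glove_stream) > 0L) {
    parsed <- parse_glove_stream(glove_stream, sensor)
    fingers <- Filter(function(f) inherits(f, "finger_frame") && f$plausible,
                      parsed$frames)
    last_g <- NA_character_
    for (j in seq_along(fingers)) {
      gid <- gesture_from_bends(fingers[[j]]$angles_deg)
      if (!is.na(gid) && (is.na(last_g) || gid != last_g)) {
        m_events[[length(m_events) + 1L]] <- structure(
          list(gesture_id = gid, source = "glove",
               t = (j - 1L) / glove_frame_hz),
          class = "gesture_command"
        )
        last_g <- gid
      }
    }
  }
  ev_df <- rbind(
    if (length(v_events) > 0L) {
      data.frame(t = vapply(v_events, `[[`, numeric(1), "t"),
                 channel = "virtual_hand",
                 gesture_id = vapply(v_events, `[[`, character(1),
                                     "gesture_id"))
    },
    if (length(m_events) > 0L) {
      data.frame(t = vapply(m_events, `[[`, numeric(1), "t"),
                 channel = "manipulator",
                 gesture_id = vapply(m_events, `[[`, character(1),
                                     "gesture_id"))
    }
  )
  if (is.null(ev_df)) {
    ev_df <- data.frame(t = numeric(0), channel = character(0),
                        gesture_id = character(0))
  }
  dev <- timing_deviation(v_events, m_events,
                          stimulus_duration_s = window_s)
  matched <- dev$deviation_pct[dev$matched]
  structure(
    list(
      events = ev_df,
      deviations = dev,
      summary = list(
        n_virtual = length(v_events),
        n_manipulator = length(m_events),
        n_matched = sum(dev$matched),
        frac_within_20pct = if (length(matched) > 0L) {
          mean(abs(matched) < 20)
        } else {
          NA_real_
        }
      ),
      errors = errors
    ),
    class = "session_report"
  )
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf(
    "<session_report> %d virtual / %d manipulator events, %d matched\n",
    x$summary$n_virtual, x$summary$n_manipulator, x$summary$n_matched))
  if (!is.na(x$summary$frac_within_20pct)) {
    cat(sprintf("  |deviation| < 20%%: %.0f%% of matched pairs\n",
                100 * x$summary$frac_within_20pct))
  }
  if (length(x$errors) > 0L) {
    cat("  errors:\n")
    for (e in x$errors) cat("   ", e, "\n")
  }
  invisible(x)
}
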