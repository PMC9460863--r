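#' Judge the emotion quadrant of one feature vector
#'
#' Deterministic rule cascade over the calibrated, normalized optimal
#' features:
#' 1. normalize `range`, `bpnn50`, `d1mean` by the model's training
#'    min-max (values outside \[-0.5, 1.5\] raise an out-of-domain warning
#'    and are clamped);
#' 2. arousal — if normalized range >= `theta_A`, the directional judgment
#'    resolves which of the two opposite high-range trends is present:
#'    arousal is high when `direction >= 0`, low otherwise; when the range
#'    is below `theta_A`, arousal is high iff normalized first-difference
#'    mean >= `theta_1d`;
#' 3. valence — positive iff normalized BpNN50 >= `theta_V`;
#' 4. compose the quadrant.
#'
#' Ties at a threshold resolve to the `>=` branch; `direction == 0` is
#' grouped with the `>= 0` (rising) branch.
#'
#' @param fv A `feature_vector` from [extract_features()] (or a list with
#'   `bpnn50`, `range`, `d1mean`, `direction`).
#' @param model A `calibration_model`.
#' @param rules Optional replacement rule cascade: a
#'   `function(norm, direction, thresholds)` returning
#'   `list(arousal =, valence =, fired =)`, so alternative decision
#'   flowcharts can be swapped in.
#' @return List with `label` (an [emotion_label()]) and `trace` (a
#'   `judgment_trace`: normalized inputs, ordered fired rule ids, output).
#' @export
judge_segment <- function(fv, model, rules = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  need <- c("bpnn50", "range", "d1mean", "direction")
  miss <- need[!vapply(need, function(f) !is.null(fv[[f]]) && is.finite(fv[[f]]),
                       logical(1))]
  if (length(miss) > 0L) {
    stop_emg("schema_error", "feature vector missing: %s",
             paste(miss, collapse = ", "))
  }
  nrm <- vapply(c("range", "bpnn50", "d1mean"), function(f) {
    p <- model$normalization[[f]]
    v <- (fv[[f]] - p[["min"]]) / (p[["max"]] - p[["min"]])
    if (v < -0.5 || v > 1.5) {
      warn_emg("out_of_domain",
               "normalized %s = %.3f outside [-0.5, 1.5]; clamped", f, v)
      v <- min(max(v, -0.5), 1.5)
    }
    v
  }, numeric(1))
  names(nrm) <- c("range", "bpnn50", "d1mean")
  th <- model$thresholds
  decide <- if (is.null(rules)) default_judge_rules else rules
  res <- decide(nrm, fv$direction, th)
  lab <- emotion_label(quadrant_from_axes(res$arousal, res$valence))
  trace <- structure(
    list(inputs = c(nrm, direction = fv$direction),
         fired_rules = res$fired, output = lab),
    class = "judgment_trace"
  )
  list(label = lab, trace = trace)
}

# The default rule cascade (see judge_segment docs).
default_judge_rules <- function(norm, direction, thresholds) {
  fired <- character(0)
  if (norm[["range"]] >= thresholds[["theta_A"]]) {
    if (direction >= 0) {
      arousal <- "high"
      fired <- c(fired, "R1: range>=theta_A & direction>=0 -> arousal high")
    } else {
      arousal <- "low"
      fired <- c(fired, "R2: range>=theta_A & direction<0 -> arousal low")
    }
  } else if (norm[["d1mean"]] >= thresholds[["theta_1d"]]) {
    arousal <- "high"
    fired <- c(fired, "R3: range<theta_A & d1mean>=theta_1d -> arousal high")
  } else {
    arousal <- "low"
    fired <- c(fired, "R4: range<theta_A & d1mean<theta_1d -> arousal low")
  }
  if (norm[["bpnn50"]] >= thresholds[["theta_V"]]) {
    valence <- "positive"
    fired <- c(fired, "R5: bpnn50>=theta_V -> valence positive")
  } else {
    valence <- "negative"
    fired <- c(fired, "R6: bpnn50<theta_V -> valence negative")
  }
  list(arousal = arousal, valence = valence, fired = fired)
}

#' @export
print.judgment_trace <- function(x, ...) {
  cat("<judgment_trace> ->", x$output$quadrant, "\n")
  for (r in x$fired_rules) cat("  ", r, "\n")
  invisible(x)
}

#' Judge a stream of feature vectors with majority smoothing
#'
#' Per-segment judgments followed by a sliding majority vote over an odd
#' window; ties keep the segment's own label. Window ends are truncated.
#'
#' @param fvs List of feature vectors.
#' @param model A `calibration_model`.
#' @param smoothing Odd window length in segments (1 = no smoothing).
#' @return Character vector of quadrant codes, one per input segment.
#' @export
judge_stream <- function(fvs, model, smoothing = 1L) {
  if (smoothing < 1L || smoothing %% 2L == 0L) {
    stop_emg("parameter_error", "smoothing must be odd and >= 1")
  }
  if (length(fvs) == 0L) return(character(0))
  raw <- vapply(fvs, function(fv) judge_segment(fv, model)$label$quadrant,
                character(1))
  if (smoothing == 1L) return(raw)
  half <- (smoothing - 1L) %/% 2L
  out <- raw
  for (i in seq_along(raw)) {
    win <- raw[max(1L, i - half):min(length(raw), i + half)]
    tab <- table(win)
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (raw[i] %in% top) raw[i] else top[1L]
  }
  out
}
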