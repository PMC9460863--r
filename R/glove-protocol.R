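#' Bending-sensor and ADC model
#'
#' Electrical model of the glove's finger-bending channel: a flex sensor in
#' a voltage divider against `divider_kohm`, read by a 12-bit ADC at
#' `v_ref` volts. The sensor's printed calibration points are 9 kOhm
#' straight, 14 kOhm at 90 degrees and 22 kOhm at 180 degrees.
#'
#' @param v_ref ADC reference voltage (V).
#' @param adc_levels Number of quantization levels (4096 = 12 bit).
#' @param divider_kohm Fixed divider resistor (kOhm).
#' @param r_straight,r_90,r_180 Sensor resistance (kOhm) at 0/90/180
#'   degrees; must be strictly increasing.
#' @param length_cm Physical sensor length (informational).
#' @param inverted If TRUE, bend angle decreases with resistance (the
#'   alternative reading of the sensor datasheet); default FALSE follows
#'   the divider equations, under which counts increase with bending.
#' @param frame_mode `"wide"` (default): a1..a5 carried as two bytes each,
#'   little-endian, 12-byte frame; `"strict7"`: one byte per finger
#'   (counts right-shifted 4 bits), the literal 7-byte frame layout.
#' @return A `sensor_model` list.
#' @export
sensor_model <- function(v_ref = 3.3, adc_levels = 4096L, divider_kohm = 20,
                         r_straight = 9, r_90 = 14, r_180 = 22,
                         length_cm = 7.7, inverted = FALSE,
                         frame_mode = c("wide", "strict7")) {
  frame_mode <- match.arg(frame_mode)
  if (!(r_straight < r_90 && r_90 < r_180)) {
    stop_emg("parameter_error",
             "calibration resistances must satisfy r_straight < r_90 < r_180")
  }
  structure(
    list(v_ref = v_ref, adc_levels = as.integer(adc_levels),
         divider_kohm = divider_kohm, r_straight = r_straight,
         r_90 = r_90, r_180 = r_180, length_cm = length_cm,
         inverted = inverted, frame_mode = frame_mode),
    class = "sensor_model"
  )
}

#' ADC count from sensor resistance
#'
#' Divider voltage `V_x = v_ref * r / (r + divider)` quantized to
#' `round(V_x * adc_levels / v_ref) = round(adc_levels * r / (r + divider))`;
#' strictly increasing in r.
#'
#' @param r Sensor resistance in kOhm (> 0).
#' @param model A [sensor_model()].
#' @return Integer ADC count.
#' @export
#' @examples
#' adc_from_resistance(9)   # 1271
#' adc_from_resistance(14)  # 1687
#' adc_from_resistance(22)  # 2146
adc_from_resistance <- function(r, model = sensor_model()) {
  if (any(r <= 0)) stop_emg("parameter_error", "resistance must be positive")
  as.integer(round(model$adc_levels * r / (r + model$divider_kohm)))
}

#' Sensor resistance from ADC count
#'
#' Inverts the divider model: `r = divider * x / (adc_levels - x)`.
#'
#' @param x ADC count, 0 < x < adc_levels (the divider can never reach
#'   full scale).
#' @param model A [sensor_model()].
#' @return Resistance in kOhm.
#' @export
resistance_from_adc <- function(x, model = sensor_model()) {
  if (any(x <= 0) || any(x >= model$adc_levels)) {
    stop_emg("out_of_range", "ADC count must lie strictly in (0, %d)",
             model$adc_levels)
  }
  model$divider_kohm * x / (model$adc_levels - x)
}

#' Bend angle from sensor resistance
#'
#' Piecewise-linear interpolation through the three printed calibration
#' points (9 kOhm, 0 deg), (14 kOhm, 90 deg), (22 kOhm, 180 deg), clamped
#' to \[0, 180\] degrees.
#'
#' @param r Resistance in kOhm (> 0).
#' @param model A [sensor_model()].
#' @return Bend angle in degrees.
#' @export
bend_angle <- function(r, model = sensor_model()) {
  if (any(r <= 0)) stop_emg("parameter_error", "resistance must be positive")
  ang <- stats::approx(
    x = c(model$r_straight, model$r_90, model$r_180), y = c(0, 90, 180),
    xout = r, rule = 2
  )$y
  if (model$inverted) ang <- 180 - ang
  ang
}

# Inverse of bend_angle on [0, 180] (used by the synthetic stream encoder).
resistance_from_bend <- function(deg, model = sensor_model()) {
  if (any(deg < 0) || any(deg > 180)) {
    stop_emg("parameter_error", "bend angle must lie in [0, 180] degrees")
  }
  if (model$inverted) deg <- 180 - deg
  stats::approx(
    x = c(0, 90, 180),
    y = c(model$r_straight, model$r_90, model$r_180),
    xout = deg, rule = 2
  )$y
}

FINGER_HEAD <- as.raw(0xaa)
FINGER_TAIL <- as.raw(0xbb)
IMU_HEAD <- as.raw(0x55)
IMU_TYPES <- c(accel = 0x51, gyro = 0x52, angle = 0x53)

#' Encode a finger-bending frame
#'
#' Frame layout `0xaa a1 a2 a3 a4 a5 0xbb` (thumb to little finger). In the
#' default `"wide"` mode each of a1..a5 is a 12-bit ADC count carried as
#' two bytes little-endian (12-byte frame); in `"strict7"` mode each count
#' is right-shifted to 8 bits and carried in one byte (7-byte frame).
#'
#' @param counts Integer vector of 5 ADC counts in \[0, 4095\].
#' @param model A [sensor_model()] (controls `frame_mode`).
#' @return Raw vector (the frame).
#' @export
encode_finger_frame <- function(counts, model = sensor_model()) {
  counts <- as.integer(counts)
  if (length(counts) != 5L) {
    stop_emg("parameter_error", "a finger frame carries exactly 5 counts")
  }
  if (any(counts < 0L) || any(counts >= model$adc_levels)) {
    stop_emg("out_of_range", "ADC counts must lie in [0, %d]",
             model$adc_levels - 1L)
  }
  payload <- if (model$frame_mode == "wide") {
    as.raw(as.vector(rbind(counts %% 256L, counts %/% 256L)))
  } else {
    as.raw(counts %/% 16L)
  }
  c(FINGER_HEAD, payload, FINGER_TAIL)
}

#' Decode one finger-bending frame
#'
#' Validates the 0xaa/0xbb framing, extracts the five counts, and applies
#' the plausibility judgment: every decoded bend angle must fall within
#' \[0, 180\] degrees plus `tol_deg`; implausible frames are flagged
#' (`plausible = FALSE`), not dropped.
#'
#' @param bytes Raw vector starting at the frame head.
#' @param model A [sensor_model()].
#' @param tol_deg Plausibility tolerance in degrees (default 5).
#' @return A `finger_frame`: `counts` (5 ADC counts), `angles_deg`
#'   (decoded bends), `plausible`, `n_bytes` consumed.
#' @export
decode_finger_frame <- function(bytes, model = sensor_model(), tol_deg = 5) {
  flen <- finger_frame_length(model)
  if (length(bytes) < flen) {
    stop_emg("framing_error", "need %d bytes for a finger frame", flen)
  }
  if (bytes[1] != FINGER_HEAD || bytes[flen] != FINGER_TAIL) {
    stop_emg("framing_error", "bad finger-frame head/tail")
  }
  body <- as.integer(bytes[2:(flen - 1L)])
  counts <- if (model$frame_mode == "wide") {
    body[c(1, 3, 5, 7, 9)] + 256L * body[c(2, 4, 6, 8, 10)]
  } else {
    body * 16L
  }
  if (any(counts >= model$adc_levels)) {
    stop_emg("framing_error", "payload exceeds ADC range")
  }
  safe <- pmin(pmax(counts, 1L), model$adc_levels - 1L)
  ang <- bend_angle(resistance_from_adc(safe, model), model)
  # raw interpolation without clamping, to judge plausibility
  r <- resistance_from_adc(safe, model)
  slope_lo <- 90 / (model$r_90 - model$r_straight)
  slope_hi <- 90 / (model$r_180 - model$r_90)
  raw_ang <- ifelse(r < model$r_straight, (r - model$r_straight) * slope_lo,
             ifelse(r > model$r_180, 180 + (r - model$r_180) * slope_hi, ang))
  plausible <- all(raw_ang >= -tol_deg & raw_ang <= 180 + tol_deg) &&
    all(counts > 0L)
  structure(
    list(counts = counts, angles_deg = ang, plausible = plausible,
         n_bytes = flen),
    class = "finger_frame"
  )
}

finger_frame_length <- function(model = sensor_model()) {
  if (model$frame_mode == "wide") 12L else 7L
}

#' Byte-sum checksum of a 10-byte frame prefix
#'
#' Sum of the 10 bytes preceding SUM, truncated to the low 8 bits.
#'
#' @param bytes Raw vector of exactly 10 bytes (header, type byte and the
#'   8 data bytes).
#' @return A single raw byte.
#' @export
#' @examples
#' imu_checksum(as.raw(c(0x55, 0x51, rep(0, 8))))  # 0xa6
imu_checksum <- function(bytes) {
  if (length(bytes) != 10L) {
    stop_emg("parameter_error", "checksum is computed over exactly 10 bytes")
  }
  as.raw(sum(as.integer(bytes)) %% 256L)
}

#' Encode an 11-byte IMU packet
#'
#' Layout `0x55 <type> XL XH YL YH ZL ZH TL TH SUM`: header 0x55, type
#' byte 0x51 (acceleration), 0x52 (angular velocity) or 0x53 (angle),
#' three signed 16-bit little-endian words, the TL/TH auxiliary word, and
#' the byte-sum checksum. Physical values are quantized by the de-facto
#' scale for this packet family: angle = word / 32768 * 180 deg,
#' acceleration = word / 32768 * 16 g, angular velocity =
#' word / 32768 * 2000 deg/s.
#'
#' @param type One of `"accel"`, `"gyro"`, `"angle"`.
#' @param values Numeric length-3 vector in physical units (g, deg/s or
#'   deg), or integer words if `as_words = TRUE`.
#' @param tl_th 16-bit auxiliary word (default 0).
#' @param as_words If TRUE `values` are raw signed 16-bit words.
#' @return Raw vector of 11 bytes.
#' @export
encode_imu_frame <- function(type = c("accel", "gyro", "angle"), values,
                             tl_th = 0L, as_words = FALSE) {
  type <- match.arg(type)
  if (length(values) != 3L) {
    stop_emg("parameter_error", "an IMU packet carries exactly 3 values")
  }
  full <- imu_full_scale(type)
  words <- if (as_words) as.integer(values) else
    as.integer(round(values / full * 32768))
  words <- pmin(pmax(words, -32768L), 32767L)
  u <- ifelse(words < 0L, words + 65536L, words)
  tl_th <- as.integer(tl_th) %% 65536L
  body <- as.raw(c(0x55, IMU_TYPES[[type]],
                   as.vector(rbind(u %% 256L, u %/% 256L)),
                   tl_th %% 256L, tl_th %/% 256L))
  c(body, imu_checksum(body))
}

imu_full_scale <- function(type) {
  switch(type, accel = 16, gyro = 2000, angle = 180)
}

#' Decode an 11-byte IMU packet
#'
#' Parses and validates one packet: header must be 0x55, the type byte one
#' of 0x51/0x52/0x53, and SUM must equal the low byte of the sum of the
#' preceding 10 bytes. The three signed words are converted to physical
#' units (see [encode_imu_frame()]).
#'
#' @param bytes Raw vector starting at the packet head (>= 11 bytes).
#' @return An `imu_frame`: `packet_type`, `raw_words` (signed 16-bit),
#'   `values` (physical units), `tl_th`, `checksum_ok`, `fields` (the 11
#'   received data bytes named angle_data0..angle_data10), `n_bytes`.
#' @export
decode_imu_frame <- function(bytes) {
  if (length(bytes) < 11L) {
    stop_emg("framing_error", "need 11 bytes for an IMU packet")
  }
  frame <- bytes[1:11]
  if (frame[1] != IMU_HEAD) {
    stop_emg("framing_error", "IMU packet must start with 0x55")
  }
  tb <- as.integer(frame[2])
  type <- names(IMU_TYPES)[match(tb, IMU_TYPES)]
  if (is.na(type)) {
    stop_emg("not_imu_packet",
             "type byte 0x%02x is not an IMU packet type", tb)
  }
  expected <- imu_checksum(frame[1:10])
  if (frame[11] != expected) {
    stop_emg("checksum_error",
             "checksum mismatch: got 0x%02x, expected 0x%02x",
             as.integer(frame[11]), as.integer(expected))
  }
  b <- as.integer(frame)
  u <- b[c(3, 5, 7)] + 256L * b[c(4, 6, 8)]
  words <- ifelse(u >= 32768L, u - 65536L, u)
  fields <- b
  names(fields) <- paste0("angle_data", 0:10)
  structure(
    list(
      packet_type = type,
      raw_words = words,
      values = words / 32768 * imu_full_scale(type),
      tl_th = b[9] + 256L * b[10],
      checksum_ok = TRUE,
      fields = fields,
      n_bytes = 11L
    ),
    class = "imu_frame"
  )
}

#' Parse a mixed glove byte stream
#'
#' Scans a raw stream for finger frames (0xaa ... 0xbb) and IMU packets
#' (0x55 + type + checksum), resynchronizing after garbage: on any framing
#' or checksum failure the parser advances one byte and retries at the
#' next candidate head byte. Invalid IMU checksums and implausible finger
#' frames are counted.
#'
#' @param bytes Raw vector.
#' @param model A [sensor_model()].
#' @return List with `frames` (decoded `finger_frame`/`imu_frame` objects
#'   with a `$offset` byte position each), and counters `n_finger`,
#'   `n_imu`, `n_checksum_errors`, `n_implausible`, `n_skipped_bytes`.
#' @export
parse_glove_stream <- function(bytes, model = sensor_model()) {
  frames <- list()
  n_ck <- 0L; n_imp <- 0L; n_skip <- 0L
  i <- 1L
  n <- length(bytes)
  flen <- finger_frame_length(model)
  while (i <= n) {
    b <- bytes[i]
    consumed <- 0L
    if (b == FINGER_HEAD && i + flen - 1L <= n) {
      fr <- tryCatch(decode_finger_frame(bytes[i:(i + flen - 1L)], model),
                     emg_error = function(e) NULL)
      if (!is.null(fr)) {
        fr$offset <- i
        if (!fr$plausible) n_imp <- n_imp + 1L
        frames[[length(frames) + 1L]] <- fr
        consumed <- fr$n_bytes
      }
    } else if (b == IMU_HEAD && i + 10L <= n) {
      fr <- tryCatch(decode_imu_frame(bytes[i:(i + 10L)]),
                     emg_error = function(e) {
                       if (inherits(e, "emg_checksum_error")) {
                         n_ck <<- n_ck + 1L
                       }
                       NULL
                     })
      if (!is.null(fr)) {
        fr$offset <- i
        frames[[length(frames) + 1L]] <- fr
        consumed <- fr$n_bytes
      }
    }
    if (consumed == 0L) {
      n_skip <- n_skip + 1L
      i <- i + 1L
    } else {
      i <- i + consumed
    }
  }
  kinds <- vapply(frames, function(f) class(f)[1], character(1))
  list(
    frames = frames,
    n_finger = sum(kinds == "finger_frame"),
    n_imu = sum(kinds == "imu_frame"),
    n_checksum_errors = n_ck,
    n_implausible = n_imp,
    n_skipped_bytes = n_skip
  )
}
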