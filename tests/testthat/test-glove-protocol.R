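test_that("ADC counts at the printed calibration resistances", {
  # independent arithmetic: x = round(4096 r / (r + 20))
  expect_equal(adc_from_resistance(9), round(4096 * 9 / 29))
  expect_equal(adc_from_resistance(9), 1271L)
  expect_equal(adc_from_resistance(14), 1687L)
  expect_equal(adc_from_resistance(22), 2146L)
  expect_error(adc_from_resistance(0), class = "emg_parameter_error")
})

test_that("resistance inverts the ADC map", {
  expect_equal(resistance_from_adc(1271), 9, tolerance = 0.01)
  for (x in seq(1, 4000, by = 100)) {
    r <- resistance_from_adc(x)
    expect_lte(abs(adc_from_resistance(r) - x), 1L)
  }
  xs <- seq(100, 4000, by = 50)
  expect_true(all(diff(resistance_from_adc(xs)) > 0))
  expect_error(resistance_from_adc(0), class = "emg_out_of_range")
  expect_error(resistance_from_adc(4096), class = "emg_out_of_range")
})

test_that("bend angle interpolates the printed calibration points", {
  expect_equal(bend_angle(9), 0)
  expect_equal(bend_angle(14), 90)
  expect_equal(bend_angle(22), 180)
  expect_equal(bend_angle(11.5), 45)
  expect_equal(bend_angle(30), 180)  # clamped
  expect_equal(bend_angle(5), 0)     # clamped
  inv <- sensor_model(inverted = TRUE)
  expect_equal(bend_angle(9, inv), 180)
  expect_equal(bend_angle(22, inv), 0)
})

test_that("finger frames round-trip through the codec", {
  set.seed(41)
  for (k in 1:100) {
    counts <- sample(0:4095, 5)
    fr <- decode_finger_frame(encode_finger_frame(counts))
    expect_identical(fr$counts, as.integer(counts))
  }
  # strict 7-byte mode: one byte per finger, 4-bit quantization
  m7 <- sensor_model(frame_mode = "strict7")
  bytes <- encode_finger_frame(c(0, 1000, 2000, 3000, 4095), m7)
  expect_length(bytes, 7L)
  fr <- decode_finger_frame(bytes, m7)
  expect_true(all(abs(fr$counts - c(0, 1000, 2000, 3000, 4095)) < 16))
})

test_that("finger frame validation flags bad framing and implausible bends", {
  good <- encode_finger_frame(rep(1500L, 5))
  bad <- good
  bad[1] <- as.raw(0x00)
  expect_error(decode_finger_frame(bad), class = "emg_framing_error")
  expect_error(decode_finger_frame(good[1:5]), class = "emg_framing_error")
  # a count implying far beyond 180 degrees of bend is implausible
  weird <- encode_finger_frame(c(4000L, rep(1500L, 4)))
  fr <- decode_finger_frame(weird)
  expect_false(fr$plausible)
  expect_true(decode_finger_frame(good)$plausible)
})

test_that("the byte-sum checksum matches the frame equations", {
  expect_identical(imu_checksum(as.raw(c(0x55, 0x51, rep(0, 8)))),
                   as.raw(0xa6))
  expect_identical(imu_checksum(as.raw(c(0x55, 0x53, rep(0, 8)))),
                   as.raw(0xa8))
  # permutation invariance of the payload sum
  set.seed(7)
  payload <- as.raw(sample(0:255, 8))
  a <- imu_checksum(c(as.raw(0x55), as.raw(0x52), payload))
  b <- imu_checksum(c(as.raw(0x55), as.raw(0x52), sample(payload)))
  expect_identical(a, b)
  # incrementing one byte increments the checksum mod 256
  p2 <- payload
  p2[3] <- as.raw((as.integer(p2[3]) + 1) %% 256)
  c2 <- imu_checksum(c(as.raw(0x55), as.raw(0x52), p2))
  expect_equal((as.integer(c2) - as.integer(a)) %% 256, 1)
  expect_error(imu_checksum(raw(9)), class = "emg_parameter_error")
})

test_that("an all-zero angle packet decodes to zero angles with SUM 0xa8", {
  frame <- encode_imu_frame("angle", c(0, 0, 0))
  expect_identical(frame[11], as.raw(0xa8))
  dec <- decode_imu_frame(frame)
  expect_equal(dec$packet_type, "angle")
  expect_equal(dec$values, c(0, 0, 0))
  expect_identical(names(dec$fields), paste0("angle_data", 0:10))
})

test_that("the angle scale maps word 0x4000 to 90 degrees", {
  frame <- encode_imu_frame("angle", c(16384, 0, 0), as_words = TRUE)
  expect_equal(decode_imu_frame(frame)$values[1], 90)
})

test_that("IMU packets round-trip within quantization for all three types", {
  set.seed(19)
  for (k in 1:100) {
    type <- sample(c("accel", "gyro", "angle"), 1)
    full <- c(accel = 16, gyro = 2000, angle = 180)[[type]]
    vals <- stats::runif(3, -full, full) * 0.99
    dec <- decode_imu_frame(encode_imu_frame(type, vals,
                                             tl_th = sample(0:65535, 1)))
    expect_equal(dec$packet_type, type)
    expect_true(all(abs(dec$values - vals) <= full / 32768))
  }
})

test_that("every single-byte corruption of a valid packet is rejected", {
  frame <- encode_imu_frame("gyro", c(100, -250, 33))
  for (pos in 1:11) {
    orig <- as.integer(frame[pos])
    for (v in setdiff(0:255, orig)) {
      bad <- frame
      bad[pos] <- as.raw(v)
      expect_error(decode_imu_frame(bad), class = "emg_error")
    }
  }
})

test_that("unknown type bytes are rejected as non-IMU packets", {
  frame <- encode_imu_frame("angle", c(1, 2, 3))
  frame[2] <- as.raw(0x54)
  frame[11] <- imu_checksum(frame[1:10])
  expect_error(decode_imu_frame(frame), class = "emg_not_imu_packet")
})

test_that("the stream parser resynchronizes across garbage", {
  set.seed(23)
  frames <- list(
    encode_finger_frame(sample(0:4095, 5)),
    encode_imu_frame("angle", c(10, -20, 30)),
    encode_finger_frame(sample(0:4095, 5)),
    encode_imu_frame("accel", c(0.5, -1, 0.25))
  )
  garbage <- function(n) as.raw(sample(0:255, n, replace = TRUE))
  stream <- c(garbage(13), frames[[1]], garbage(5), frames[[2]],
              frames[[3]], garbage(8), frames[[4]], garbage(3))
  parsed <- parse_glove_stream(stream)
  expect_gte(parsed$n_finger, 2L)
  expect_gte(parsed$n_imu, 2L)
  decoded_counts <- lapply(
    Filter(function(f) inherits(f, "finger_frame"), parsed$frames),
    `[[`, "counts"
  )
  expect_true(all(vapply(
    list(decode_finger_frame(frames[[1]])$counts,
         decode_finger_frame(frames[[3]])$counts),
    function(cnt) any(vapply(decoded_counts, identical, logical(1), cnt)),
    logical(1)
  )))
})

test_that("corrupted checksums are counted, valid frames still recovered", {
  f1 <- encode_imu_frame("angle", c(10, 20, 30))
  bad <- f1
  bad[11] <- as.raw((as.integer(bad[11]) + 1) %% 256)
  f2 <- encode_imu_frame("angle", c(-10, -20, -30))
  parsed <- parse_glove_stream(c(bad, f2))
  expect_equal(parsed$n_imu, 1L)
  expect_gte(parsed$n_checksum_errors, 1L)
})
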