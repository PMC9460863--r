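test_that("quiet preset yields a constant baseline trace", {
  s <- gen_gsr(quiet_preset(), duration_s = 10, seed = 3, baseline = 5)
  expect_equal(s$values, rep(5, length(s$values)))
  expect_equal(s$fs, 20)
})

test_that("gsr generation is deterministic in the seed", {
  p <- default_presets()$HANV
  a <- gen_gsr(p, duration_s = 15, seed = 11)
  b <- gen_gsr(p, duration_s = 15, seed = 11)
  c <- gen_gsr(p, duration_s = 15, seed = 12)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
})

test_that("pure tonic drift rises by slope times duration", {
  p <- quadrant_preset("HANV", scr_rate = 0, scr_amp = 0,
                       trend_slope = 0.5, hrv_pnn50_target = 0,
                       mean_hr = 60, noise_sd = 0)
  s <- gen_gsr(p, duration_s = 30, seed = 1)
  expect_equal(s$values[length(s$values)] - s$values[1], 15.0)
})

test_that("gsr generator rejects non-positive duration and fs", {
  p <- quiet_preset()
  expect_error(gen_gsr(p, duration_s = -1), class = "emg_parameter_error")
  expect_error(gen_gsr(p, fs = 0), class = "emg_parameter_error")
})

test_that("metronomic ppg yields zero BpNN50 and the expected beat count", {
  s <- gen_ppg(quiet_preset(mean_hr = 60), duration_s = 30, seed = 5,
               noise_sd = 0)
  beats <- detect_beats(lowpass_pulse(s))
  expect_gte(length(beats$peaks), 25)
  expect_lte(length(beats$peaks), 35)
  expect_equal(bpnn50(beats), 0)
})

test_that("ppg requires a sampling rate that resolves the notch", {
  expect_error(gen_ppg(quiet_preset(), fs = 30),
               class = "emg_parameter_error")
})

test_that("every noise-free beat shows one dicrotic notch", {
  s <- gen_ppg(quiet_preset(mean_hr = 70), duration_s = 20, seed = 2,
               noise_sd = 0)
  beats <- detect_beats(s)
  tab <- fiducial_table(s, beats)
  expect_true(all(!tab$degenerate))
  # exactly one interior local minimum between systolic and dicrotic peak
  for (k in seq_len(nrow(tab))) {
    span <- tab$c[k]:tab$g[k]
    x <- s$values[span]
    mins <- which(diff(sign(diff(x))) > 0) + 1L
    expect_equal(length(mins), 1L)
  }
})

test_that("labeled datasets are balanced and seed-reproducible", {
  ds <- gen_labeled_dataset(default_presets(), n_per_class = 5, seed = 9,
                            duration_s = 5)
  labs <- vapply(ds$segments, `[[`, character(1), "label")
  expect_length(ds$segments, 20L)
  expect_true(all(table(labs) == 5L))
  ds2 <- gen_labeled_dataset(default_presets(), n_per_class = 5, seed = 9,
                             duration_s = 5)
  expect_identical(ds$segments[[1]]$gsr$values, ds2$segments[[1]]$gsr$values)
  ds3 <- gen_labeled_dataset(default_presets(), n_per_class = 5, seed = 10,
                             duration_s = 5)
  expect_false(identical(ds$segments[[1]]$gsr$values,
                         ds3$segments[[1]]$gsr$values))
})

test_that("duplicate quadrants in the preset list are rejected", {
  p <- default_presets()
  p$LAPV <- p$HANV
  expect_error(gen_labeled_dataset(p, n_per_class = 2),
               class = "emg_parameter_error")
})

test_that("high-arousal presets produce the largest skin-electrical range", {
  ds <- gen_labeled_dataset(default_presets(), n_per_class = 25, seed = 1,
                            duration_s = 30)
  rng <- vapply(ds$segments, function(s) {
    diff(range(s$gsr$values))
  }, numeric(1))
  labs <- vapply(ds$segments, `[[`, character(1), "label")
  class_mean <- tapply(rng, labs, mean)
  high <- class_mean[c("HANV", "HAPV")]
  low <- class_mean[c("LANV", "LAPV")]
  expect_true(min(high) > max(low))
})

test_that("glove stream encoding round-trips bends and angles", {
  expect_identical(gen_glove_stream(), raw(0))

  one <- gen_glove_stream(finger_bends = matrix(0, 1, 5))
  expect_identical(one[1], as.raw(0xaa))
  expect_identical(one[length(one)], as.raw(0xbb))

  set.seed(31)
  for (k in 1:100) {
    bends <- matrix(stats::runif(5, 0, 180), 1, 5)
    angs <- matrix(stats::runif(3, -180, 180), 1, 3)
    stream <- gen_glove_stream(bends, angs, seed = k)
    parsed <- parse_glove_stream(stream)
    expect_equal(parsed$n_finger, 1L)
    expect_equal(parsed$n_imu, 1L)
    ff <- parsed$frames[[1]]
    im <- parsed$frames[[2]]
    expect_true(all(abs(ff$angles_deg - bends[1, ]) < 0.5))
    expect_true(all(abs(im$values - angs[1, ]) < 2 * 180 / 32768))
  }
})

test_that("out-of-range bends and angles are rejected by the encoder", {
  expect_error(gen_glove_stream(finger_bends = matrix(200, 1, 5)),
               class = "emg_parameter_error")
  expect_error(gen_glove_stream(imu_angles = matrix(181, 1, 3)),
               class = "emg_parameter_error")
})

test_that("session signals concatenate one block per quadrant", {
  ss <- gen_session_signals(order = c("HANV", "LAPV"), seed = 4,
                            block_s = 10)
  expect_equal(signal_duration(ss$gsr), 20)
  expect_equal(signal_duration(ss$pulse), 20)
  expect_equal(ss$labels, c("HANV", "LAPV"))
})
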