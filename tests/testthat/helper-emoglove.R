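# Shared fixtures, all built in code.

# A preset with no phasic events, no drift and no noise: generates a flat
# skin-electrical trace and metronomic beats.
quiet_preset <- function(label = "LANV", mean_hr = 60) {
  quadrant_preset(label, scr_rate = 0, scr_amp = 0, trend_slope = 0,
                  hrv_pnn50_target = 0, mean_hr = mean_hr, noise_sd = 0)
}

# Minimal hand-built calibration model on the unit scale: normalization is
# the identity on [0, 1] and all three thresholds sit at 0.5. Lets the
# judge's rule cascade be exercised with literal normalized inputs.
unit_model <- function(theta_A = 0.5, theta_V = 0.5, theta_1d = 0.5) {
  structure(
    list(
      selected_features = c("range", "bpnn50", "d1mean"),
      pca = NULL, pcc = NULL,
      normalization = list(
        range = c(min = 0, max = 1),
        bpnn50 = c(min = 0, max = 1),
        d1mean = c(min = 0, max = 1)
      ),
      thresholds = c(theta_A = theta_A, theta_V = theta_V,
                     theta_1d = theta_1d),
      config = list(),
      schema_version = 1L
    ),
    class = "calibration_model"
  )
}

fv_unit <- function(range, bpnn50, d1mean, direction) {
  list(range = range, bpnn50 = bpnn50, d1mean = d1mean,
       direction = direction)
}

# Feature table with gaussian class-conditional structure mirroring the
# generator's assumptions, for calibration tests that do not need the full
# signal pipeline.
separable_table <- function(n_per_class = 10, seed = 42, sd_frac = 0.05) {
  means <- list(
    HAPV = c(range = 3.5, bpnn50 = 55, d1mean = 0.003),
    HANV = c(range = 3.5, bpnn50 = 10, d1mean = 0.003),
    LANV = c(range = 0.8, bpnn50 = 12, d1mean = -0.001),
    LAPV = c(range = 0.8, bpnn50 = 58, d1mean = -0.001)
  )
  set.seed(seed)
  rows <- lapply(names(means), function(q) {
    m <- means[[q]]
    data.frame(
      segment_id = seq_len(n_per_class), label = q,
      bpnn50 = pmax(0, m["bpnn50"] + stats::rnorm(n_per_class, sd = 3)),
      range = pmax(0.01, m["range"] * (1 + stats::rnorm(n_per_class,
                                                        sd = sd_frac))),
      d1mean = m["d1mean"] + stats::rnorm(n_per_class, sd = 2e-4),
      direction = if (substr(q, 1, 1) == "H") 1L else -1L
    )
  })
  tab <- do.call(rbind, rows)
  tab$segment_id <- seq_len(nrow(tab))
  tab
}

# Brute-force Pearson r and two-sided P from the covariance formula,
# independent of stats::cor.test.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  r <- (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  c(r = r, p = p)
}
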