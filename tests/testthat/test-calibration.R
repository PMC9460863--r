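test_that("identical feature columns load equally on the first component", {
  set.seed(1)
  f <- rnorm(30)
  tab <- data.frame(label = rep(quadrant_levels(), length.out = 30),
                    a = f, b = f, c = rnorm(30))
  sel <- pca_select_features(tab, feature_cols = c("a", "b", "c"))
  expect_equal(abs(sel$loadings["a", 1]), abs(sel$loadings["b", 1]),
               tolerance = 1e-10)
})

test_that("a correlated signal block is selected over isolated noise", {
  # two features sharing the label-driven component form the dominant
  # correlated direction; an independent noise feature loads on its own
  # later component, which a first-component cut excludes
  set.seed(14)
  n <- 100
  lab01 <- rep(c(1, 0), each = n / 2)
  tab <- data.frame(
    f1 = 2 * lab01 + rnorm(n, sd = 0.2),
    f2 = 2 * lab01 + rnorm(n, sd = 0.2),
    f3 = rnorm(n)
  )
  sel <- pca_select_features(tab, variance_keep = 0.6,
                             weight_threshold = 0.6,
                             feature_cols = c("f1", "f2", "f3"))
  expect_true(all(c("f1", "f2") %in% sel$selected))
  expect_false("f3" %in% sel$selected)
})

test_that("permissive thresholds select every non-constant feature", {
  tab <- separable_table(5)
  sel <- pca_select_features(tab, variance_keep = 1.0, weight_threshold = 0,
                             feature_cols = c("bpnn50", "range", "d1mean"))
  expect_setequal(sel$selected, c("bpnn50", "range", "d1mean"))
})

test_that("constant feature columns are dropped with a warning", {
  tab <- separable_table(5)
  tab$flat <- 1
  expect_warning(
    sel <- pca_select_features(tab,
                               feature_cols = c("bpnn50", "range", "flat")),
    class = "emg_constant_feature"
  )
  expect_false("flat" %in% rownames(sel$loadings))
})

test_that("PCA selection needs at least three segments", {
  tab <- separable_table(5)[1:2, ]
  expect_error(pca_select_features(tab), class = "emg_insufficient_data")
})

test_that("PCA selection is invariant to per-feature affine rescaling", {
  tab <- separable_table(8, seed = 3)
  sel1 <- pca_select_features(tab, feature_cols = c("bpnn50", "range",
                                                    "d1mean"))
  tab2 <- tab
  tab2$range <- tab2$range * 1000 + 7
  tab2$bpnn50 <- tab2$bpnn50 / 50 - 2
  sel2 <- pca_select_features(tab2, feature_cols = c("bpnn50", "range",
                                                     "d1mean"))
  expect_setequal(sel1$selected, sel2$selected)
  expect_equal(abs(sel1$loadings), abs(sel2$loadings), tolerance = 1e-8)
})

test_that("a feature equal to the quadrant indicator correlates perfectly", {
  tab <- separable_table(4, seed = 8)
  tab$ind <- as.numeric(tab$label == "HAPV")
  pcc <- pcc_emotion(tab, feature_cols = "ind")
  r_hapv <- pcc$r[pcc$quadrant == "HAPV"]
  expect_equal(r_hapv, 1.0, tolerance = 1e-12)
})

test_that("correlation is antisymmetric under indicator flips", {
  tab <- separable_table(6, seed = 12)
  pcc <- pcc_emotion(tab, feature_cols = "range")
  ind <- as.numeric(tab$label == "HANV")
  r_direct <- stats::cor(tab$range, ind)
  r_flipped <- stats::cor(tab$range, 1 - ind)
  expect_equal(pcc$r[pcc$quadrant == "HANV"], r_direct, tolerance = 1e-12)
  expect_equal(r_flipped, -r_direct, tolerance = 1e-12)
})

test_that("label-independent features are rarely significant", {
  set.seed(55)
  hits <- 0L
  for (rep in 1:50) {
    labs <- rep(quadrant_levels(), each = 50)
    x <- rnorm(200)
    ind <- as.numeric(labs == "LANV")
    ct <- stats::cor.test(x, ind)
    if (abs(ct$estimate) < 0.2 && ct$p.value > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("pcc_emotion matches the covariance-formula oracle", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(8:50, 1)
    labs <- c(quadrant_levels(), quadrant_levels(),
              sample(quadrant_levels(), n - 8, replace = TRUE))
    tab <- data.frame(label = labs, x = rnorm(n), y = rnorm(n))
    pcc <- pcc_emotion(tab, feature_cols = c("x", "y"))
    for (i in seq_len(nrow(pcc))) {
      ind <- as.numeric(labs == pcc$quadrant[i])
      o <- pearson_oracle(tab[[pcc$feature[i]]], ind)
      expect_equal(pcc$r[i], unname(o["r"]), tolerance = 1e-10)
      expect_equal(pcc$p[i], unname(o["p"]), tolerance = 1e-10)
    }
  }
})

test_that("calibration separates well-separated classes perfectly", {
  tab <- separable_table(10, seed = 20)
  model <- fit_calibration(tab)
  fvs <- lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, ]))
  pred <- judge_stream(fvs, model)
  expect_equal(mean(pred == tab$label), 1.0)
})

test_that("theta_A depends only on the arousal partition", {
  tab <- separable_table(10, seed = 33)
  m1 <- fit_calibration(tab)
  swapped <- tab
  swapped$label[tab$label == "HANV"] <- "HAPV"
  swapped$label[tab$label == "HAPV"] <- "HANV"
  m2 <- fit_calibration(swapped)
  expect_equal(m1$thresholds["theta_A"], m2$thresholds["theta_A"])
})

test_that("thresholds lie strictly between the class medians", {
  tab <- separable_table(10, seed = 44)
  m <- fit_calibration(tab)
  nrm <- function(f, v) {
    p <- m$normalization[[f]]
    (v - p[["min"]]) / (p[["max"]] - p[["min"]])
  }
  high <- tab$label %in% c("HANV", "HAPV")
  med_hi <- stats::median(nrm("range", tab$range[high]))
  med_lo <- stats::median(nrm("range", tab$range[!high]))
  th <- m$thresholds[["theta_A"]]
  expect_true(th > min(med_hi, med_lo) && th < max(med_hi, med_lo))
})

test_that("calibration requires all four quadrants", {
  tab <- separable_table(5)
  expect_error(fit_calibration(tab[tab$label != "LANV", ]),
               class = "emg_insufficient_data")
})

test_that("calibration models survive a JSON round trip", {
  tab <- separable_table(6, seed = 2)
  m <- fit_calibration(tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(m, path)
  m2 <- read_calibration(path)
  expect_equal(m2$thresholds, m$thresholds, tolerance = 1e-12)
  expect_equal(m2$normalization, m$normalization, tolerance = 1e-12)
  expect_setequal(m2$selected_features, m$selected_features)
  fv <- fv_unit(2, 30, 0.001, 1)
  expect_equal(judge_segment(fv, m2)$label$quadrant,
               judge_segment(fv, m)$label$quadrant)
})
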