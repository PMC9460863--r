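#' PCA-based feature selection by loading threshold
#'
#' Standardizes the feature columns, runs principal component analysis,
#' retains the smallest set of leading components reaching
#' `variance_keep` cumulative explained variance, and selects every feature
#' whose maximum absolute loading over the retained components is at least
#' `weight_threshold`. At least one feature is always selected (the one
#' with the largest loading wins if none clears the threshold). Constant
#' feature columns are dropped with a warning.
#'
#' @param table Feature table (data frame); `feature_cols` names its
#'   numeric feature columns.
#' @param variance_keep Cumulative explained-variance fraction to retain
#'   (default 0.85).
#' @param weight_threshold Absolute-loading selection threshold (default
#'   0.6).
#' @param feature_cols Character vector of feature column names; defaults
#'   to all numeric columns except `segment_id`/`direction`.
#' @return List with `selected` (names), `loadings` (feature x retained
#'   component matrix), `explained` (per-component variance fractions),
#'   `n_components`.
#' @export
pca_select_features <- function(table, variance_keep = 0.85,
                                weight_threshold = 0.6,
                                feature_cols = NULL) {
  if (is.null(feature_cols)) {
    num <- vapply(table, is.numeric, logical(1))
    feature_cols <- setdiff(names(table)[num], c("segment_id", "direction"))
  }
  if (length(feature_cols) < 2L) {
    stop_emg("insufficient_data", "need at least 2 feature columns")
  }
  if (nrow(table) < 3L) {
    stop_emg("insufficient_data", "need at least 3 segments for PCA")
  }
  x <- as.matrix(table[, feature_cols, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warn_emg("constant_feature", "dropping constant feature column(s): %s",
             paste(feature_cols[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    feature_cols <- colnames(x)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- which(cumsum(expl) >= variance_keep - 1e-12)[1]
  load <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  wmax <- apply(abs(load), 1, max)
  selected <- feature_cols[wmax >= weight_threshold]
  if (length(selected) == 0L) selected <- feature_cols[which.max(wmax)]
  list(selected = selected, loadings = load,
       explained = expl[seq_len(ncomp)], n_components = ncomp)
}

#' Pearson correlation of features with emotion trends
#'
#' For each feature and each quadrant, the Pearson correlation between the
#' feature values and the one-vs-rest indicator of that quadrant, with the
#' two-sided significance P from the t transform of r on n - 2 degrees of
#' freedom (`stats::cor.test`). Zero-variance features get missing r/P.
#'
#' @param table Labeled feature table with a `label` column.
#' @param feature_cols Feature column names (default as in
#'   [pca_select_features()]).
#' @return Data frame with columns `feature`, `quadrant`, `r`, `p`.
#' @export
pcc_emotion <- function(table, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    num <- vapply(table, is.numeric, logical(1))
    feature_cols <- setdiff(names(table)[num], c("segment_id", "direction"))
  }
  labs <- as.character(table$label)
  counts <- table(factor(labs, levels = quadrant_levels()))
  if (any(counts < 2L)) {
    stop_emg("insufficient_data",
             "each quadrant needs at least 2 segments for correlation")
  }
  grid <- expand.grid(feature = feature_cols, quadrant = quadrant_levels(),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- table[[grid$feature[i]]]
    ind <- as.numeric(labs == grid$quadrant[i])
    if (stats::sd(x) == 0 || stats::sd(ind) == 0) {
      return(c(r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, ind, method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  cbind(grid, do.call(rbind, res))
}

#' Fit the quadrant-judgment calibration model
#'
#' From a labeled feature table: runs PCA selection and Pearson screening
#' for the record, min-max normalizes the three optimal features (range,
#' BpNN50, first-difference mean) over the training data, and sets the
#' decision thresholds as midpoints of class-conditional medians on the
#' normalized scale:
#' * `theta_A` — normalized range, high-arousal vs low-arousal classes;
#' * `theta_V` — normalized BpNN50, positive vs negative valence classes;
#' * `theta_1d` — normalized first-difference mean, high vs low arousal.
#'
#' @param table Labeled feature table containing all four quadrants.
#' @param variance_keep,weight_threshold Passed to [pca_select_features()].
#' @param alpha Significance level recorded with the correlation screen.
#' @return A `calibration_model`: selection results, correlation table,
#'   per-feature normalization `(min, max)`, thresholds, and the
#'   configuration used.
#' @export
fit_calibration <- function(table, variance_keep = 0.85,
                            weight_threshold = 0.6, alpha = 0.05) {
  labs <- as.character(table$label)
  if (!setequal(unique(labs), quadrant_levels())) {
    stop_emg("insufficient_data",
             "all four quadrants must be present in the training table")
  }
  sel <- pca_select_features(table, variance_keep, weight_threshold)
  pcc <- pcc_emotion(table)
  optimal <- c("range", "bpnn50", "d1mean")
  norm <- lapply(optimal, function(f) {
    rng <- range(table[[f]])
    if (rng[1] == rng[2]) {
      stop_emg("degenerate_input", "feature '%s' is constant in training", f)
    }
    c(min = rng[1], max = rng[2])
  })
  names(norm) <- optimal
  nrm <- function(f, v) {
    (v - norm[[f]]["min"]) / (norm[[f]]["max"] - norm[[f]]["min"])
  }
  med <- function(f, classes) {
    stats::median(nrm(f, table[[f]][labs %in% classes]))
  }
  high <- c("HANV", "HAPV"); low <- c("LANV", "LAPV")
  pos <- c("HAPV", "LAPV"); neg <- c("HANV", "LANV")
  thresholds <- c(
    theta_A = unname((med("range", high) + med("range", low)) / 2),
    theta_V = unname((med("bpnn50", pos) + med("bpnn50", neg)) / 2),
    theta_1d = unname((med("d1mean", high) + med("d1mean", low)) / 2)
  )
  structure(
    list(
      selected_features = union(sel$selected, optimal),
      pca = sel,
      pcc = pcc,
      normalization = norm,
      thresholds = thresholds,
      config = list(variance_keep = variance_keep,
                    weight_threshold = weight_threshold, alpha = alpha),
      schema_version = 1L
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>\n")
  cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
  cat(sprintf("  thresholds: theta_A=%.3f theta_V=%.3f theta_1d=%.3f\n",
              x$thresholds["theta_A"], x$thresholds["theta_V"],
              x$thresholds["theta_1d"]))
  invisible(x)
}

#' Serialize a calibration model to JSON
#'
#' @param model A `calibration_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- list(
    schema_version = model$schema_version,
    selected_features = model$selected_features,
    thresholds = as.list(model$thresholds),
    normalization = lapply(model$normalization, as.list),
    pca = list(selected = model$pca$selected,
               explained = model$pca$explained,
               n_components = model$pca$n_components,
               loadings = as.data.frame(model$pca$loadings)),
    pcc = model$pcc,
    config = model$config
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a calibration model from JSON
#'
#' @param path JSON file written by [write_calibration()].
#' @return A `calibration_model`.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop_emg("format_error", "unsupported calibration schema version")
  }
  norm <- lapply(obj$normalization, function(v) unlist(v))
  structure(
    list(
      selected_features = obj$selected_features,
      pca = list(selected = obj$pca$selected,
                 explained = obj$pca$explained,
                 n_components = obj$pca$n_components,
                 loadings = as.matrix(as.data.frame(obj$pca$loadings))),
      pcc = as.data.frame(obj$pcc),
      normalization = norm,
      thresholds = unlist(obj$thresholds),
      config = obj$config,
      schema_version = 1L
    ),
    class = "calibration_model"
  )
}
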