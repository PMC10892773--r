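# Per-channel statistics (population-normalized) and the within-triad
# Pearson correlations that summarise one 1.5 s window.
PD_CHANNEL_STATS <- c("std", "var", "skew", "kurt", "rms", "energy",
                      "median", "range")
PD_TRIAD_PAIRS <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L),
                       c(4L, 5L), c(4L, 6L), c(5L, 6L))

#' Names of the 54 window features, in canonical order
#'
#' 8 statistics for each of the 6 channels, then the 6 within-triad
#' correlations (3 accelerometer pairs, 3 gyroscope pairs).
#' @param correlation_scope `"triad"` (default, 6 pairs) or `"all_pairs"`
#'   (all 15 channel pairs).
#' @return character vector of feature names.
#' @export
feature_names <- function(correlation_scope = c("triad", "all_pairs")) {
  correlation_scope <- match.arg(correlation_scope)
  base <- as.vector(t(outer(CHANNEL_NAMES, PD_CHANNEL_STATS, paste, sep = "_")))
  pairs <- if (correlation_scope == "triad") PD_TRIAD_PAIRS else
    utils::combn(6, 2, simplify = FALSE)
  cors <- vapply(pairs, function(p)
    paste0("cor_", CHANNEL_NAMES[p[1]], "_", CHANNEL_NAMES[p[2]]), "")
  c(base, cors)
}

#' Extract the feature vector of one window
#'
#' Per channel: population standard deviation, variance, skewness (Fisher,
#' population), excess kurtosis (Fisher, population; normal -> 0), RMS,
#' energy (sum of squares, = n * RMS^2), median and range; plus Pearson
#' correlations within the accelerometer and gyroscope triads.  A
#' zero-variance channel yields 0 for skewness, kurtosis and any
#' correlation involving it, with a warning.
#'
#' @param segment a `pd_window`.
#' @param correlation_scope `"triad"` or `"all_pairs"`.
#' @return object of class `pd_window_feature`: the segment metadata plus
#'   a named numeric `vector`.
#' @export
extract_window_features <- function(segment,
                                    correlation_scope = c("triad", "all_pairs")) {
  correlation_scope <- match.arg(correlation_scope)
  x <- segment$samples
  if (!all(is.finite(x)))
    pd_stop("window contains non-finite samples", "pdmil_error_nonfinite")
  v <- window_feature_row(x, correlation_scope)
  structure(list(subject_id = segment$subject_id,
                 activity_id = segment$activity_id,
                 window_index = segment$window_index,
                 vector = v),
            class = "pd_window_feature")
}

window_feature_row <- function(x, correlation_scope = "triad") {
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  m2 <- colMeans(xc^2)
  m3 <- colMeans(xc^3)
  m4 <- colMeans(xc^4)
  sdv <- sqrt(m2)
  zerovar <- sdv == 0
  if (any(zerovar))
    pd_warn("zero-variance channel in window; shape stats set to 0",
            "pdmil_warning_zero_variance")
  skew <- ifelse(zerovar, 0, m3 / sdv^3)
  kurt <- ifelse(zerovar, 0, m4 / m2^2 - 3)
  rms <- sqrt(colMeans(x^2))
  energy <- colSums(x^2)
  med <- matrixStats::colMedians(x)
  rng <- matrixStats::colRanges(x)
  rng <- rng[, 2] - rng[, 1]
  stats <- rbind(sdv, m2, skew, kurt, rms, energy, med, rng)
  pairs <- if (correlation_scope == "triad") PD_TRIAD_PAIRS else
    utils::combn(6, 2, simplify = FALSE)
  cors <- vapply(pairs, function(p) {
    if (zerovar[p[1]] || zerovar[p[2]]) return(0)
    mean(xc[, p[1]] * xc[, p[2]]) / (sdv[p[1]] * sdv[p[2]])
  }, numeric(1))
  out <- c(as.vector(stats), cors)
  names(out) <- feature_names(correlation_scope)
  out
}

#' Window-feature table for a whole cohort
#'
#' Runs filter -> normalize -> segment -> featurize for every recording of
#' the requested activities and stacks the results.
#'
#' @param cohort a `pd_cohort`.
#' @param activities activity ids to include (default: all in the cohort).
#' @param config preprocessing / feature config (see
#'   [preprocess_recording()]; additionally `features.correlation_scope`).
#' @return data.frame with columns `subject_id`, `activity_id`,
#'   `window_index`, `severity` and the 54 feature columns.
#' @export
cohort_features <- function(cohort, activities = NULL, config = NULL) {
  activities <- activities %||% cohort$config$activities
  scope <- (config$features$correlation_scope) %||% "triad"
  sev <- stats::setNames(cohort$subjects$severity, cohort$subjects$subject_id)
  rows <- list()
  for (key in names(cohort$recordings)) {
    rec <- cohort$recordings[[key]]
    if (!rec$activity_id %in% activities) next
    segs <- preprocess_recording(rec, config)
    if (length(segs) == 0) next
    fm <- t(vapply(segs, function(s) window_feature_row(s$samples, scope),
                   numeric(length(feature_names(scope)))))
    meta <- data.frame(subject_id = rec$subject_id,
                       activity_id = rec$activity_id,
                       window_index = vapply(segs, `[[`, integer(1),
                                             "window_index"),
                       severity = sev[[rec$subject_id]],
                       stringsAsFactors = FALSE)
    rows[[key]] <- cbind(meta, as.data.frame(fm))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

feature_columns <- function(features) {
  setdiff(names(features),
          c("subject_id", "activity_id", "window_index", "severity"))
}
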